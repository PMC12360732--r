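form,lemma
better,good
best,good
worse,bad
worst,bad
went,go
gone,go
goes,go
going,go
was,be
were,be
is,be
are,be
am,be
been,be
being,be
has,have
had,have
having,have
did,do
does,do
done,do
said,say
says,say
got,get
gotten,get
made,make
took,take
taken,take
saw,see
seen,see
came,come
knew,know
known,know
thought,think
felt,feel
left,leave
told,tell
met,meet
found,find
gave,give
given,give
ran,run
men,man
women,woman
children,child
people,person
feet,foot
teeth,tooth
mice,mouse
partying,party
partied,party
parties,party
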