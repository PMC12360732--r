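{
  "social": ["friend*", "buddy", "buddies", "bro", "mate*", "talk*", "chat*",
             "call*", "text*", "meet*", "hang*", "together", "party*",
             "family", "brother*", "sister*", "everyone", "people", "crowd"],
  "affect": ["happy", "happi*", "love*", "lovin*", "great", "good", "nice",
             "sweet", "excit*", "fun", "glad", "sad", "cry*", "hate*",
             "angry", "mad", "scared", "afraid", "awesome", "terrible",
             "miss*", "hurt*"],
  "drives": ["work*", "win*", "goal*", "achiev*", "success*", "plan*",
             "effort*", "try*", "power*", "lead*", "better", "improve*",
             "money", "earn*", "job*", "career*", "gym", "grind*"],
  "cognitive_processes": ["think*", "thought*", "know*", "because", "cause",
                          "reason*", "maybe", "perhaps", "wonder*",
                          "understand*", "realiz*", "guess*", "sure",
                          "question*", "figur*", "remember*", "decide*",
                          "should", "why"]
}
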