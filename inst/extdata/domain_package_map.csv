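domain,package
facebook.com,com.facebook.katana
m.facebook.com,com.facebook.katana
instagram.com,com.instagram.android
twitter.com,com.twitter.android
x.com,com.twitter.android
reddit.com,com.reddit.frontpage
old.reddit.com,com.reddit.frontpage
web.whatsapp.com,com.whatsapp
web.telegram.org,org.telegram.messenger
tiktok.com,com.zhiliaoapp.musically
tumblr.com,com.tumblr
grindr.com,com.grindrapp.android
tinder.com,com.tinder
adam4adam.com,com.a4a.adam4adam
bumble.com,com.bumble.app
okcupid.com,com.okcupid.okcupid
messenger.com,com.facebook.orca
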