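package,category
com.google.android.apps.messaging,messaging
com.whatsapp,messaging
org.telegram.messenger,messaging
com.facebook.orca,messaging
org.thoughtcrime.securesms,messaging
com.discord,messaging
com.snapchat.android,messaging
com.facebook.katana,social_media
com.instagram.android,social_media
com.twitter.android,social_media
com.reddit.frontpage,social_media
com.zhiliaoapp.musically,social_media
com.tumblr,social_media
com.grindrapp.android,dating
com.tinder,dating
com.a4a.adam4adam,dating
com.scruffapp,dating
com.bumble.app,dating
com.okcupid.okcupid,dating
com.feeld.app,dating
com.spotify.music,other
com.google.android.apps.maps,other
com.amazon.mShop.android.shopping,other
com.android.vending,other
com.netflix.mediaclient,other
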