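>An_gambiae
1 $ 2 3 4 5 6 $ 7 8 $ 9 $
>An_atroparvus
-1 $ -9 $ 6 -4 -5 $ -2 -3 -8 7 $
>An_albimanus
-1 8 $ 7 $ 6 5 -2 $ 3 -4 -9 $
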