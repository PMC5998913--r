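# Klein four-group triple as gene orders on 2 genes (n = 4 extremities)
>A
1 @
2 @
>B
-1 2 @
>C
1 2 @
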