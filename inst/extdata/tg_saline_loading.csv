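experiment_id,coil,nucleus,f0_hz,tg_db
paddles_156,paddles,NA23,,27.3
paddles_156,paddles,C13,,17.4
paddles_112,paddles,NA23,,27.6
paddles_112,paddles,C13,,17.4
paddles_75,paddles,NA23,,27.4
paddles_75,paddles,C13,,17.7
paddles_50,paddles,NA23,,27.6
paddles_50,paddles,C13,,18.2
loop_156,loop,NA23,,25.7
loop_156,loop,C13,,14.7
loop_112,loop,NA23,,25.8
loop_112,loop,C13,,14.6
loop_75,loop,NA23,,25.6
loop_75,loop,C13,,14.6
loop_50,loop,NA23,,25.8
loop_50,loop,C13,,14.7
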