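fm_id,aras_k,aras_rank,vikor_1mq,vikor_rank,waspas_k,waspas_rank
FM1,1,1,0.886001,1,0.908328,1
FM2,0.639173,9,0.490006,5,0.61668,6
FM3,0.639173,8,0.490006,6,0.61668,6
FM4,0.547233,16,0.227734,12,0.525401,14
FM5,0.641408,7,0.256854,10,0.574432,12
FM6,0.820733,2,0.788539,2,0.768887,2
FM7,0.449923,19,0.023046,20,0.427602,19
FM8,0.597983,13,0.094016,17,0.505932,15
FM9,0.597983,13,0.097349,16,0.505932,15
FM10,0.697882,5,0.52666,4,0.669031,4
FM11,0.800098,3,0.653339,3,0.746237,3
FM12,0.639173,9,0.490006,6,0.61668,6
FM13,0.639173,9,0.490006,6,0.61668,6
FM14,0.618537,12,0.443694,9,0.596717,10
FM15,0.41857,20,0.060223,19,0.408149,20
FM16,0.556623,15,0.170121,13,0.527339,13
FM17,0.477278,18,0.097572,15,0.464974,18
FM18,0.656759,6,0.250875,11,0.594369,11
FM19,0.732604,4,0.158472,14,0.661489,5
FM20,0.519892,17,0.085798,18,0.488624,17
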