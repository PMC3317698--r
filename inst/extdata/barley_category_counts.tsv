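category	unique	reads
miRNA	23239	625232
rRNA	83300	1006189
repeat	23642	90970
snRNA	3020	15180
snoRNA	1872	6711
tRNA	16957	1154444
unannotated	3893194	6641836
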