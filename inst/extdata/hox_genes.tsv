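gene	cluster
HOXA1	HOXA
HOXA2	HOXA
HOXA3	HOXA
HOXA4	HOXA
HOXA5	HOXA
HOXA6	HOXA
HOXA7	HOXA
HOXA9	HOXA
HOXA10	HOXA
HOXA11	HOXA
HOXA13	HOXA
HOXB1	HOXB
HOXB2	HOXB
HOXB3	HOXB
HOXB4	HOXB
HOXB5	HOXB
HOXB6	HOXB
HOXB7	HOXB
HOXB8	HOXB
HOXB9	HOXB
HOXB13	HOXB
HOXC4	HOXC
HOXC5	HOXC
HOXC6	HOXC
HOXC8	HOXC
HOXC9	HOXC
HOXC10	HOXC
HOXC11	HOXC
HOXC12	HOXC
HOXC13	HOXC
HOXD1	HOXD
HOXD3	HOXD
HOXD4	HOXD
HOXD8	HOXD
HOXD9	HOXD
HOXD10	HOXD
HOXD11	HOXD
HOXD12	HOXD
HOXD13	HOXD
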