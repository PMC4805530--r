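subfamily	active
L1Hs	TRUE
L1PA2	FALSE
L1PA3	FALSE
L1PA4	FALSE
L1PA5	FALSE
L1PA6	FALSE
L1PA7	FALSE
L1PA8	FALSE
L1PA9	FALSE
L1PA10	FALSE
L1PA11	FALSE
L1PA12	FALSE
L1PA13	FALSE
L1PA14	FALSE
L1PA15	FALSE
L1PA16	FALSE
L1PA17	FALSE
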