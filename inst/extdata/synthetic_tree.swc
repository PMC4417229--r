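# generated by purkinje2c::write_swc
1 1 0 0 0 11 -1
2 3 138.258612 0 0 2.78701511 1
3 3 285.170273 0 0 2.84268853 2
4 3 387.563793 0 0 1.21534884 3
5 3 434.610479 0 0 2.57611907 3
6 3 473.411278 0 0 2.1043638 3
7 3 453.540982 0 0 1.79773987 4
8 3 241.47132 0 0 2.34147079 2
9 3 327.461226 0 0 0.836666493 2
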