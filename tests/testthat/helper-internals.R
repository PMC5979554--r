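# engine-level internals exercised directly by the tests
search_run <- hivedock:::search_run
abc_generation <- hivedock:::abc_generation
de_generation <- hivedock:::de_generation
random_gvec <- hivedock:::random_gvec
repair_vec <- hivedock:::repair_vec
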