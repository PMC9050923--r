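token	smiles	n_atoms	ring_kind
Ph	c2ccccc2	6	phenyl
2-FC6H4	c2ccccc2F	7	phenyl
3-FC6H4	c2cccc(F)c2	7	phenyl
4-FC6H4	c2ccc(F)cc2	7	phenyl
2-ClC6H4	c2ccccc2Cl	7	phenyl
3-ClC6H4	c2cccc(Cl)c2	7	phenyl
4-ClC6H4	c2ccc(Cl)cc2	7	phenyl
4-BrC6H4	c2ccc(Br)cc2	7	phenyl
3-MeC6H4	c2cccc(C)c2	7	phenyl
4-MeC6H4	c2ccc(C)cc2	7	phenyl
2-MeOC6H4	c2ccccc2OC	8	phenyl
4-MeOC6H4	c2ccc(OC)cc2	8	phenyl
4-CF3OC6H4	c2ccc(OC(F)(F)F)cc2	11	phenyl
4-CF3C6H4	c2ccc(C(F)(F)F)cc2	10	phenyl
4-iPrC6H4	c2ccc(C(C)C)cc2	9	phenyl
4-tBuC6H4	c2ccc(C(C)(C)C)cc2	10	phenyl
4-Me2NC6H4	c2ccc(N(C)C)cc2	9	phenyl
4-BnOC6H4	c2ccc(OCc3ccccc3)cc2	14	phenyl
2-Thienyl	c2cccs2	5	thienyl
3-Pyridyl	c2cnccc2	6	pyridyl
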