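{
  "syn_cebpb": 1.34431533652631,
  "syn_pparg": 0.569391018199658,
  "syn_cebpa": 0.177687588455491,
  "syn_pakt": 0.153786771606507,
  "syn_ir": 0.019989965563441,
  "syn_fat": 3,
  "deg_cebpb": 0.0631861108867897,
  "deg_pparg": 0.0433496541097041,
  "deg_cebpa": 0.0743336376036547,
  "deg_pakt": 0.5,
  "deg_ir": 0.05,
  "deg_fat": 0.12,
  "base_cebpb": 0.0219234584565047,
  "base_pparg": 0.0761333648127612,
  "base_cebpa": 0.189767512543047,
  "base_ir": 2.25125493419776,
  "alpha1": 6.23490302679771,
  "alpha2": 11.7176463123853,
  "alpha3": 0.589531802489809,
  "alpha4": 1.5,
  "alpha5": 0.130190170361054,
  "alpha6": 3,
  "alpha7": 8,
  "alpha8": 40,
  "rosi_gain": 13.1851372739158,
  "rosi_k": 1
}
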