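{
  "comment": "SYNTHETIC reference acyltransferase (AT) domain scaffold: fixed randomly drawn sequence with 24 active-site signature positions; stands in for a curated AT reference profile.",
  "reference_sequence": "KTAIIDEAKERTMIVYPDFPDLLLFSNSLINQGINQSQVLIISFKVGQDDGVLHELEWPISKPRTTFGAGAYSEGLMDMGFLMVQRPCERALFDNGRIFGQGHRNNQPFLTPKTAQEKFQGLTADQKEALPHNQVMFLEKYGNKIPDGEITEFIPAFFMVVFRLLVTYSVDYQTVEQVVDNDIAYTARWHGSSQKLNCLARPEDLYENSLQAAARGFEGASSVLAYSKTEAMQRTPAPESSNAHLTVVETLERANPQLAIPADSGTNGGQMPLSLIHLKDNLIVRYYVISLNIAAALAIA",
  "signature_positions": [83, 87, 96, 100, 110, 125, 127, 130, 133, 137, 139, 147, 163, 165, 193, 194, 205, 208, 211, 221, 223, 234, 235, 250]
}
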