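{
  "comment": "SYNTHETIC reference A-domain scaffold: a fixed randomly drawn sequence standing in for a curated reference structure; Stachelhaus positions follow the GrsA numbering convention.",
  "reference_sequence": "SNASSEVIIQSPMKTTAKTNAVSLVKKSMVQDPIASHHSGPLSSDSVKESQTLGHVTATEKMSTDVLGLHCWFIKILSKLGHSTVTSRERQSTIHVSRIVDPEVLTAKLDHEREYDHEVVVSLFTGDNRRWNKEGEDPRCAFKLLSPKYAVDVAYKVLLAKGLTFPTSASKSMIDVVSAACDTLREMETRPKDVKLPCVRFRITRAIVTGQCRSMRAACTDADQAIVEAYIRRGLNRKQYHQVDNNRLMPLEKSFGPVKPQLVAIILRAAYVKKAYNTLTWGEQSELVYYTGHLLMINGQDQRKPVDLSIALVSSEHATQPQTLLLRMDSDPGASESRTDIRVHKGRVVRCVVLIIVPEARLIYLAESGLVFTMERKAVLEASPDTLIEKPHLESPLAREIYATKVLQIAIFSKMDTPDESWMLKLVTEDAPTAKDDEGTGDGHAKTGIVASGSTDIIDLLFVHFDVKQHISLENAPVDEAGHEALMLAIFCRNRLALLLTKKGANAFDKPSALGYVGLG",
  "stachelhaus_positions": [235, 236, 239, 278, 299, 301, 322, 330, 331, 517],
  "signature_positions": [234, 235, 236, 237, 238, 239, 240, 243, 247, 251, 255, 270, 275, 278, 282, 286, 290, 295, 299, 301, 305, 310, 315, 322, 326, 330, 331, 335, 340, 350, 365, 380, 400, 517]
}
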