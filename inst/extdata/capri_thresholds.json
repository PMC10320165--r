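{
  "version": "1.0",
  "comment": "CAPRI accuracy tiers. Each tier requires fnat >= fnat_min AND (lrmsd <= lrmsd_max OR irmsd <= irmsd_max); tiers are tested from High down and the first satisfied tier is assigned, else Incorrect. protein_protein follows the standard CAPRI protein-protein table; peptide follows the CAPRI protein-peptide table used to flag displaced peptides.",
  "protein_protein": {
    "High":       {"fnat_min": 0.5, "lrmsd_max": 1.0,  "irmsd_max": 1.0},
    "Medium":     {"fnat_min": 0.3, "lrmsd_max": 5.0,  "irmsd_max": 2.0},
    "Acceptable": {"fnat_min": 0.1, "lrmsd_max": 10.0, "irmsd_max": 4.0}
  },
  "peptide": {
    "High":       {"fnat_min": 0.8, "lrmsd_max": 1.0,  "irmsd_max": 0.5},
    "Medium":     {"fnat_min": 0.5, "lrmsd_max": 2.0,  "irmsd_max": 1.0},
    "Acceptable": {"fnat_min": 0.2, "lrmsd_max": 5.0,  "irmsd_max": 2.0}
  },
  "contact_cutoff": 5.0,
  "interface_cutoff": 10.0
}
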