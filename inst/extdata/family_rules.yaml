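# Default E3 family / substrate-receptor classification rules.
#
# For each family, `domains` and `motifs` list claim strings that are
# sufficient for membership when present as domain/literature evidence;
# `partners` lists interaction partners sufficient when present as
# interaction evidence; `supporting` lists claims that are tallied as
# supporting evidence but are not sufficient on their own (e.g. BTB for
# CRL3 substrate receptors, since not every BTB protein is a CRL3 SR).
# Families with all lists empty are curator-only: membership comes from
# family-context curator votes.
RING:
  domains: [RING]
  motifs: []
  partners: []
  supporting: []
dRING:
  domains: [U-box, SP-RING, hemiRING, RING-like]
  motifs: []
  partners: []
  supporting: []
HECT:
  domains: [HECT]
  motifs: []
  partners: []
  supporting: []
RBR:
  domains: [RING1, IBR, RING2]
  motifs: []
  partners: []
  supporting: []
CRL1_SR:
  domains: [F-box]
  motifs: []
  partners: [CUL1, SKP1]
  supporting: []
CRL2_SR:
  domains: []
  motifs: [BC-box-CUL2-box]
  partners: [CUL2, ELOB, ELOC]
  supporting: []
CRL3_SR:
  domains: []
  motifs: [3-box]
  partners: [CUL3]
  supporting: [BTB]
CRL4_SR:
  domains: []
  motifs: [helix-loop-helix]
  partners: [DDB1]
  supporting: []
CRL5_SR:
  domains: [SOCS-box]
  motifs: []
  partners: [CUL5, ELOB, ELOC]
  supporting: []
APCC_SR:
  domains: []
  motifs: []
  partners: []
  supporting: []
atypical:
  domains: []
  motifs: []
  partners: []
  supporting: []
pseudo:
  domains: []
  motifs: []
  partners: []
  supporting: []
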