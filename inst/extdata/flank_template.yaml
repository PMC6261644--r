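# Template specification for the Cgt flank library oligo (the same design
# that gbs_templates()$cgt builds in code), as a worked example of the
# YAML template format.
name: cgt_flank
oligo: TAGAGCATGCACCGGACACTCTTTCCCTACACGACGCTCTTCCGATCTCAGCGCAAGAACAtttTGTACGNNNNNCTAGATCGGAAGAGCACACGTCTGAACTCCAGTCACTCGACGAATTCGGCC
anchor_5p: ACACTCTTTCCCTACACGACGCTCT
anchor_3p: AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC
position_labels:
  "8": 31
  "9": 32
  "10": 33
  "11": 34
  "12": 35
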