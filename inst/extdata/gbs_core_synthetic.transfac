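ID gbs_core_synthetic
BF synthetic counts encoding the 15 bp dimeric GR consensus (AGAACAnnnTGTTCT); not derived from any database release
P0      A       C       G       T
01      85      5       5       5
02      5       5       85      5
03      85      5       5       5
04      85      5       5       5
05      5       85      5       5
06      85      5       5       5
07      25      25      25      25
08      25      25      25      25
09      25      25      25      25
10      5       5       5       85
11      5       5       85      5
12      5       5       5       85
13      5       25      5       65
14      5       85      5       5
15      5       25      5       65
XX
//
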