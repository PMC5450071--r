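chrom,n_snps,size_kbp
Pv01,533,52183.50
Pv02,792,49033.70
Pv03,623,52218.60
Pv04,389,45793.20
Pv05,431,40237.50
Pv06,532,31973.20
Pv07,537,51698.40
Pv08,656,59634.60
Pv09,523,37399.60
Pv10,401,43213.20
Pv11,529,50203.60
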