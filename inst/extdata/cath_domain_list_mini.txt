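# mini CathDomainList-style fixture (synthetic lengths and deeper levels)
# columns: domain_id C A T H S35 S60 S95 S100 count length
1lq7A00 1 20 1270 10 1 1 1 1 1 67
2oo2A00 1 20 1270 20 1 1 1 1 1 71
2qe9A01 1 20 120 10 1 1 1 1 1 142
1abcA00 2 40 50 10 1 1 1 1 1 98
1defB01 2 40 50 20 3 2 1 1 2 104
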