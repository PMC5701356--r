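>X00001|IGHV1-2*01|Homo sapiens|F|V-REGION|synthetic test segment
caggtgcagctggtgcagtctggggct...gaggtgaagaagcctggggcctcagtgaaggtc
tcctgcaaggcttctggatacaccttc............accggctactatatgcactgggtg
>X00002|IGHV3-23*01|Homo sapiens|F|V-REGION|synthetic test segment
gaggtgcagctgttggagtctggggga...ggcttggtacagcctggggggtccctgagactc
tcctgtgcagcctctggattcaccttt............agcagctatgccatgagctgggtc
>X00003|IGHV4-34*01|Homo sapiens|F|V-REGION|synthetic test segment
caggtgcagctacagcagtggggcgca...ggactgttgaagccttcggagaccctgtccctc
acctgcgctgtctatggtgggtccttc............agtggttactactggagctggatc
>X00004|IGHD3-10*01|Homo sapiens|F|D-REGION|synthetic test segment
gtattactatggttcggggagttattataac
>X00005|IGHD6-19*01|Homo sapiens|F|D-REGION|synthetic test segment
gggtatagcagtggctggtac
>X00006|IGHJ4*02|Homo sapiens|F|J-REGION|synthetic test segment
actactttgactactggggccagggaaccctggtcaccgtctcctcag
>IGHJ6*02
attactactactactacggtatggacgtctggggccaagggaccacggtcaccgtctcctca
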