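percentile,age_months,psych
25,120,8.7601
50,120,9.2878
75,120,9.5261
25,126,8.4713
50,126,9.2182
75,126,9.5261
25,132,8.1879
50,132,9.1328
75,132,9.5261
25,138,7.9099
50,138,9.0316
75,138,9.5261
25,144,7.6373
50,144,8.9146
75,144,9.5261
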