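category,label,a,b,c,d
red,immediate_referral,1857,522,204,2197
yellow,review_6_months,2996,543,465,776
green,review_1_year,3483,159,555,583
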