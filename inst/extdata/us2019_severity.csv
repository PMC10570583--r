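class,consequence,avg_cost,count
Fatal,Fatal,"1,565,000","33,244"
Major,Injury,"20,235","1,916,000"
Minor,Property,"4,711","4,806,000"
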