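"item_id","content","n_categories","a","b1","b2","b3","b4","b5","b6"
"item01","synthetic hand-function item 1","7","2.4616243904456496","-3.75","-3.0499999999999998","-2.3500000000000001","-1.6499999999999999","-0.95000000000000018","-0.25"
"item02","synthetic hand-function item 2","7","1.8302439188119024","-3.3500000000000001","-2.6499999999999999","-1.9500000000000002","-1.25","-0.55000000000000027","0.14999999999999991"
"item03","synthetic hand-function item 3","7","1.8441545441746712","-2.9500000000000002","-2.25","-1.5499999999999998","-0.84999999999999998","-0.15000000000000013","0.55000000000000004"
"item04","synthetic hand-function item 4","7","1.5721023813821375","-2.5499999999999998","-1.8499999999999996","-1.1499999999999999","-0.44999999999999984","0.25","0.95000000000000018"
"item05","synthetic hand-function item 5","7","2.2844685439486057","-2.1499999999999999","-1.4499999999999997","-0.74999999999999989","-0.049999999999999933","0.64999999999999991","1.3500000000000001"
"item06","synthetic hand-function item 6","7","2.1380803741049021","-1.75","-1.0499999999999998","-0.34999999999999998","0.34999999999999998","1.0499999999999998","1.75"
"item07","synthetic hand-function item 7","7","1.8670410409104079","-1.3499999999999996","-0.64999999999999947","0.050000000000000377","0.75000000000000033","1.4500000000000002","2.1500000000000004"
"item08","synthetic hand-function item 8","7","1.7294545061886311","-0.94999999999999973","-0.24999999999999956","0.45000000000000029","1.1500000000000004","1.8500000000000001","2.5500000000000003"
"item09","synthetic hand-function item 9","7","1.9392349401023239","-0.54999999999999982","0.15000000000000036","0.8500000000000002","1.5500000000000003","2.25","2.9500000000000002"
"item10","synthetic hand-function item 10","7","1.5172803222667426","-0.14999999999999991","0.55000000000000027","1.25","1.9500000000000002","2.6499999999999999","3.3500000000000001"
"item11","synthetic hand-function item 11","7","2.3989764184225351","0.25","0.95000000000000018","1.6499999999999999","2.3500000000000001","3.0499999999999998","3.75"
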