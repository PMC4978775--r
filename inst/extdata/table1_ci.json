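[{"parameter":"k_on","pair":"shared LCK","median":0.00089,"ci_lo":0.00068,"ci_hi":0.0019},{"parameter":"k_on_csk","pair":"shared CSK","median":0.00059,"ci_lo":0.00044,"ci_hi":0.0012},{"parameter":"k_off_1","pair":"1","median":0.1,"ci_lo":4.8e-07,"ci_hi":0.03},{"parameter":"k_off_2","pair":"2","median":490,"ci_lo":410,"ci_hi":1500},{"parameter":"k_off_3","pair":"3","median":610000,"ci_lo":97000,"ci_hi":2800000},{"parameter":"k_off_4","pair":"4","median":26000000,"ci_lo":4600,"ci_hi":28000000},{"parameter":"k_off_5","pair":"5","median":640,"ci_lo":550,"ci_hi":5100},{"parameter":"k_off_6","pair":"6","median":0.00076,"ci_lo":2.6e-05,"ci_hi":0.0015},{"parameter":"k_off_7","pair":"7","median":0.0011,"ci_lo":0.0012,"ci_hi":0.018},{"parameter":"k_off_8","pair":"8","median":0.0012,"ci_lo":0.0019,"ci_hi":0.061},{"parameter":"k_off_9","pair":"9","median":230,"ci_lo":180,"ci_hi":700},{"parameter":"k_off_10","pair":"10","median":53,"ci_lo":1.3,"ci_hi":7700},{"parameter":"k_off_11","pair":"11","median":77000,"ci_lo":1.3,"ci_hi":21000},{"parameter":"k_off_12","pair":"12","median":54,"ci_lo":10,"ci_hi":11000},{"parameter":"k_off_13","pair":"13","median":16,"ci_lo":0.0018,"ci_hi":51},{"parameter":"k_off_14","pair":"14","median":5600000,"ci_lo":1100000,"ci_hi":9100000},{"parameter":"k_off_15","pair":"15","median":2.4e-11,"ci_lo":1.8e-11,"ci_hi":9.7e-10},{"parameter":"k_off_16","pair":"16","median":1.6,"ci_lo":0.68,"ci_hi":2.5},{"parameter":"k_off_csk_uu","pair":"CSK-UU","median":0.044,"ci_lo":0.025,"ci_hi":0.086},{"parameter":"k_off_csk_pu","pair":"CSK-PU","median":1.3e-06,"ci_lo":1.4e-07,"ci_hi":1.4e-05},{"parameter":"k_cat_1","pair":"1","median":2700,"ci_lo":2100,"ci_hi":6500},{"parameter":"k_cat_2","pair":"2","median":42,"ci_lo":29,"ci_hi":84},{"parameter":"k_cat_3","pair":"3","median":7.6e-11,"ci_lo":2.5e-11,"ci_hi":5.2e-08},{"parameter":"k_cat_4","pair":"4","median":0.0022,"ci_lo":5.1e-06,"ci_hi":0.13},{"parameter":"k_cat_5","pair":"5","median":39,"ci_lo":0.54,"ci_hi":50},{"parameter":"k_cat_6","pair":"6","median":4.6e-06,"ci_lo":1.2e-08,"ci_hi":6.6e-06},{"parameter":"k_cat_7","pair":"7","median":5.9e-12,"ci_lo":8.3e-12,"ci_hi":3.8e-10},{"parameter":"k_cat_8","pair":"8","median":6.6e-11,"ci_lo":1e-11,"ci_hi":1.8e-09},{"parameter":"k_cat_9","pair":"9","median":13,"ci_lo":9.4,"ci_hi":30},{"parameter":"k_cat_10","pair":"10","median":6.3e-08,"ci_lo":1.9e-08,"ci_hi":0.0022},{"parameter":"k_cat_11","pair":"11","median":0.0095,"ci_lo":2.3e-05,"ci_hi":0.54},{"parameter":"k_cat_12","pair":"12","median":1.9e-06,"ci_lo":3.4e-07,"ci_hi":0.0001},{"parameter":"k_cat_13","pair":"13","median":920,"ci_lo":200,"ci_hi":9100},{"parameter":"k_cat_14","pair":"14","median":5.8e-11,"ci_lo":3e-12,"ci_hi":6.5e-09},{"parameter":"k_cat_15","pair":"15","median":0.00081,"ci_lo":0.00081,"ci_hi":0.00081},{"parameter":"k_cat_16","pair":"16","median":0.063,"ci_lo":9e-05,"ci_hi":0.066},{"parameter":"k_cat_csk_uu","pair":"CSK-UU","median":0.0021,"ci_lo":0.0015,"ci_hi":0.002},{"parameter":"k_cat_csk_pu","pair":"CSK-PU","median":18000000,"ci_lo":930000,"ci_hi":26000000}]
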