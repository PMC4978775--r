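{"k_on":0.00089,"k_on_csk":0.00059,"k_off_1":0.1,"k_off_2":490,"k_off_3":610000,"k_off_4":26000000,"k_off_5":640,"k_off_6":0.00076,"k_off_7":0.0011,"k_off_8":0.0012,"k_off_9":230,"k_off_10":53,"k_off_11":77000,"k_off_12":54,"k_off_13":16,"k_off_14":5600000,"k_off_15":2.4e-11,"k_off_16":1.6,"k_off_csk_uu":0.044,"k_off_csk_pu":1.3e-06,"k_cat_1":2700,"k_cat_2":42,"k_cat_3":7.6e-11,"k_cat_4":0.0022,"k_cat_5":39,"k_cat_6":4.6e-06,"k_cat_7":5.9e-12,"k_cat_8":6.6e-11,"k_cat_9":13,"k_cat_10":6.3e-08,"k_cat_11":0.0095,"k_cat_12":1.9e-06,"k_cat_13":920,"k_cat_14":5.8e-11,"k_cat_15":0.00081,"k_cat_16":0.063,"k_cat_csk_uu":0.0021,"k_cat_csk_pu":18000000}
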