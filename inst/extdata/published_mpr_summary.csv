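year,mpr_innovator_brand,mpr_generic,printed_ratio
2011,29.51,8.06,3.66
2012,33.07,8.28,3.99
2013,37.20,7.18,5.18
2014,36.57,7.05,5.19
2015,28.07,5.77,4.86
2016,34.76,5.50,6.32
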