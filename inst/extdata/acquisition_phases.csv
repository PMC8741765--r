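phase,months,dm,non_dm
1,Dec-Jan,272,258
2,Mar-May,483,267
3,Jun-Sep,723,339
4,Oct,180,153
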