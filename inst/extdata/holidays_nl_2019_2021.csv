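date,name
2019-01-01,Nieuwjaarsdag
2019-04-19,Goede Vrijdag
2019-04-21,Eerste Paasdag
2019-04-22,Tweede Paasdag
2019-04-27,Koningsdag
2019-05-05,Bevrijdingsdag
2019-05-30,Hemelvaartsdag
2019-06-09,Eerste Pinksterdag
2019-06-10,Tweede Pinksterdag
2019-12-25,Eerste Kerstdag
2019-12-26,Tweede Kerstdag
2020-01-01,Nieuwjaarsdag
2020-04-10,Goede Vrijdag
2020-04-12,Eerste Paasdag
2020-04-13,Tweede Paasdag
2020-04-27,Koningsdag
2020-05-05,Bevrijdingsdag
2020-05-21,Hemelvaartsdag
2020-05-31,Eerste Pinksterdag
2020-06-01,Tweede Pinksterdag
2020-12-25,Eerste Kerstdag
2020-12-26,Tweede Kerstdag
2021-01-01,Nieuwjaarsdag
2021-04-02,Goede Vrijdag
2021-04-04,Eerste Paasdag
2021-04-05,Tweede Paasdag
2021-04-27,Koningsdag
2021-05-05,Bevrijdingsdag
2021-05-13,Hemelvaartsdag
2021-05-23,Eerste Pinksterdag
2021-05-24,Tweede Pinksterdag
2021-12-25,Eerste Kerstdag
2021-12-26,Tweede Kerstdag
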