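period,screened_women,screened_contacts,pregnant_women,contacts
total,78941,975545,10985,39023
2019,NA,NA,4414,12384
2020,NA,NA,4553,12686
2021,NA,NA,4836,13953
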