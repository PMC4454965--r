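date,station,air_temperature,relative_humidity,solar_radiation
2014-01-28,Hobart,36.5,15,595
2014-01-16,Melbourne,43.2,16,600
2014-01-29,Sydney,29,45,713
2014-01-04,Brisbane,35.5,47,706
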