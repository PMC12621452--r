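group,metric,source,mean,sd,n,sem
bivalve,NRF6.2,ranking,192.46,,66,6.16
cephalopod,NRF6.2,ranking,131.74,,36,4.03
crustacean,NRF6.2,ranking,123.76,33.83,152,2.74
small_pelagic,NRF6.2,ranking,102.54,2.85,12,0.82
salmonid,NRF6.2,ranking,90.53,15.3,69,1.85
demersal,NRF6.2,ranking,89.55,39.9,96,4.07
gastropod,NRF6.2,ranking,84.80,,12,4.66
cichlid,NRF6.2,ranking,75.52,37.0,24,7.55
cod,NRF6.2,ranking,69.33,21.1,48,3.05
small_pelagic,NRF9.2,ranking,288.80,9.39,12,2.71
bivalve,NRF9.2,ranking,229.38,,66,5.61
cichlid,NRF9.2,ranking,219.19,17.2,24,3.51
cephalopod,NRF9.2,ranking,207.45,,132,2.53
crustacean,NRF9.2,ranking,167.19,27.27,152,2.21
cod,NRF9.2,ranking,153.33,14.6,48,2.10
salmonid,NRF9.2,ranking,151.69,28.6,69,3.45
gastropod,NRF9.2,ranking,149.97,,12,8.02
demersal,NRF9.2,ranking,120.27,39.9,96,4.07
small_pelagic,NRF6.2,group_table,103,2.85,12,0.82
cichlid,NRF6.2,group_table,75.5,37.0,24,7.55
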