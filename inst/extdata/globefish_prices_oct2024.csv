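species_group,price_per_kg,currency,yield_fraction
crab,13.33,USD,0.25
lobster,34.44,USD,0.28
shrimp_prawn,27.96,USD,0.46
crayfish,,USD,0.12
bass,6.74,USD,0.39
catfish,6.50,USD,0.19
pike,9.81,USD,0.38
cod,7.53,USD,0.38
mackerel,4.44,USD,0.54
trout,7.19,USD,0.66
salmon,8.56,USD,0.65
sole,19.71,USD,0.60
tilapia,5.10,USD,1.00
abalone,,USD,0.42
conch,7.09,USD,0.68
clam,14.72,USD,0.20
mussel,3.51,USD,0.51
oyster,17.95,USD,0.11
scallop,5.30,USD,0.13
octopus,13.11,USD,0.79
squid,7.38,USD,0.78
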