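channel	RS1like	RS2like	RS3like	RS4like	RS5like	RS6like
deletion_1-10kb	0.071794	0.05	0.05	0.157735	0.55	0.026315
deletion_10kb-1Mb	0.045008	0.15	0.02	0.068307	0.2	0.006153
deletion_>1Mb	0.018226	0.1	0.01	0.009594	0.03	0.155501
inversion_1-10kb	0.045388	0.05	0.05	0.03293	0.05	0.082641
inversion_10kb-1Mb	0.048607	0.1	0.02	0.092704	0.03	0.03852
inversion_>1Mb	0.06026	0.15	0.01	0.278309	0.02	0.402083
tandem-duplication_1-10kb	0.077314	0.05	0.7	0.126921	0.05	0.018258
tandem-duplication_10kb-1Mb	0.540605	0.1	0.08	0.073187	0.03	0.057396
tandem-duplication_>1Mb	0.045516	0.05	0.02	0.097111	0.02	0.02689
translocation	0.047281	0.2	0.04	0.063202	0.02	0.186243
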