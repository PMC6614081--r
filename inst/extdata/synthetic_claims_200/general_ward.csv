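patient_id,hospital_id,admit_date,discharge_date
P0000002,H0016,2015-04-28,2015-05-22
P0000006,H0025,2014-04-27,2014-05-09
P0000018,H0019,2014-12-09,2015-01-02
P0000032,H0007,2014-07-19,2014-08-06
P0000039,H0017,2014-05-24,2014-06-22
P0000050,H0010,2015-12-13,2016-01-10
P0000058,H0023,2015-12-16,2015-12-30
P0000060,H0024,2016-02-06,2016-03-01
P0000065,H0016,2014-05-23,2014-06-02
P0000074,H0007,2014-04-22,2014-05-06
P0000078,H0003,2015-02-20,2015-03-01
P0000087,H0011,2015-09-16,2015-10-10
P0000093,H0015,2014-03-21,2014-04-02
P0000105,H0006,2015-03-19,2015-03-26
P0000107,H0007,2014-06-19,2014-07-08
P0000119,H0016,2015-12-05,2016-01-03
P0000121,H0010,2014-12-20,2015-01-17
P0000133,H0023,2015-01-29,2015-02-27
P0000135,H0017,2014-08-28,2014-09-12
P0000136,H0001,2015-07-13,2015-07-26
P0000145,H0014,2016-02-13,2016-03-07
P0000150,H0020,2014-11-24,2014-11-27
P0000152,H0009,2015-03-04,2015-03-07
P0000154,H0006,2015-07-25,2015-08-03
P0000157,H0019,2014-11-25,2014-12-17
P0000165,H0022,2015-07-15,2015-07-29
P0000182,H0009,2014-04-02,2014-04-21
P0000198,H0003,2015-05-09,2015-05-18
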