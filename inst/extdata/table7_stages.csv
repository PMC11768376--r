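year,stage,start_date,end_date
2022,seedling,2022-05-11,2022-06-03
2022,flowering_fruiting,2022-06-04,2022-07-05
2022,full_fruiting,2022-07-06,2022-08-02
2022,later_fruiting,2022-08-03,2022-08-30
2023,seedling,2023-05-14,2023-06-01
2023,flowering_fruiting,2023-06-02,2023-06-30
2023,full_fruiting,2023-07-01,2023-07-31
2023,later_fruiting,2023-08-01,2023-08-31
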