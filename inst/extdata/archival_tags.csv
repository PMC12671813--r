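tag_id,release_date,release_lat,release_lon,fl_release_cm,recapture_date,recapture_lat,recapture_lon,fl_recapture_cm,days_at_liberty_printed
8943,2021-10-25,36.72,141.47,54,2022-04-28,33.54,136.52,,185
8950,2021-10-25,36.43,141.47,53,2022-05-19,30.83,138.67,60,206
9222,2021-11-04,36.85,141.32,54,2022-05-23,32.48,133.20,60,200
9244,2021-11-03,36.70,141.33,54,2022-06-08,33.75,139.97,61,217
8947,2021-10-25,36.72,141.47,54,2022-07-04,33.50,136.08,61,252
9147,2021-10-25,36.43,141.47,56,2022-07-07,33.94,138.82,69.5,255
9149,2021-10-25,36.72,141.47,55,2022-07-14,34.52,139.27,62,262
8312,2020-10-16,40.98,150.90,35.5,2021-05-11,32.33,136.83,45.5,208
6977,2019-10-03,39.17,143.98,50,2020-05-07,34.30,137.30,64,218
6955,2019-10-07,39.52,143.70,53,2020-05-16,33.50,139.77,,223
6962,2019-10-07,39.52,143.70,49,2020-06-02,33.42,139.58,63.1,240
6949,2019-10-07,39.68,143.62,54,2020-07-07,36.00,147.00,69,275
2737,2014-06-02,31.59,144.23,44,2014-09-09,27.37,129.43,50,100
2815,2014-06-02,31.59,144.23,43,2016-03-30,22.58,149.42,70,668
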