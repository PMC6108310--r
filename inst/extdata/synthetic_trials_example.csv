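subject_id,condition,stimulus_strength,choice,rt
example01,unadapted,0.125,happy,1.3833
example01,unadapted,0.125,happy,0.6895
example01,unadapted,0.125,happy,1.1573
example01,unadapted,0.125,happy,0.7768
example01,unadapted,0.375,sad,1.3578
example01,unadapted,0.375,happy,1.026
example01,unadapted,0.375,happy,1.1699
example01,unadapted,0.375,happy,1.083
example01,unadapted,0.475,sad,0.4031
example01,unadapted,0.475,happy,2.995
example01,unadapted,0.475,sad,1.5153
example01,unadapted,0.475,sad,1.0653
example01,unadapted,0.575,sad,1.8983
example01,unadapted,0.575,sad,0.9824
example01,unadapted,0.575,sad,0.833
example01,unadapted,0.575,happy,1.451
example01,unadapted,0.875,sad,1.1377
example01,unadapted,0.875,sad,0.889
example01,unadapted,0.875,sad,0.4702
example01,unadapted,0.875,sad,0.9666
example01,happy_adapted,0.125,happy,1.0774
example01,happy_adapted,0.125,happy,0.5089
example01,happy_adapted,0.125,happy,0.3231
example01,happy_adapted,0.125,happy,0.5582
example01,happy_adapted,0.375,happy,0.4837
example01,happy_adapted,0.375,happy,1.4339
example01,happy_adapted,0.375,sad,0.4792
example01,happy_adapted,0.375,happy,0.8473
example01,happy_adapted,0.475,happy,1.4366
example01,happy_adapted,0.475,sad,1.5348
example01,happy_adapted,0.475,happy,0.6253
example01,happy_adapted,0.475,happy,0.6946
example01,happy_adapted,0.575,happy,0.752
example01,happy_adapted,0.575,sad,0.6036
example01,happy_adapted,0.575,sad,0.2876
example01,happy_adapted,0.575,sad,0.3452
example01,happy_adapted,0.875,sad,0.322
example01,happy_adapted,0.875,sad,1.1088
example01,happy_adapted,0.875,sad,0.3067
example01,happy_adapted,0.875,sad,0.6343
example01,sad_adapted,0.125,happy,0.5771
example01,sad_adapted,0.125,happy,0.4269
example01,sad_adapted,0.125,happy,0.4243
example01,sad_adapted,0.125,happy,0.7037
example01,sad_adapted,0.375,happy,0.6543
example01,sad_adapted,0.375,happy,1.1098
example01,sad_adapted,0.375,happy,0.8218
example01,sad_adapted,0.375,happy,0.4196
example01,sad_adapted,0.475,sad,0.9309
example01,sad_adapted,0.475,sad,0.7651
example01,sad_adapted,0.475,happy,0.8693
example01,sad_adapted,0.475,happy,2.5152
example01,sad_adapted,0.575,happy,0.7075
example01,sad_adapted,0.575,happy,0.4925
example01,sad_adapted,0.575,sad,1.4954
example01,sad_adapted,0.575,sad,0.5048
example01,sad_adapted,0.875,sad,0.3932
example01,sad_adapted,0.875,sad,0.4374
example01,sad_adapted,0.875,sad,0.4357
example01,sad_adapted,0.875,sad,0.4365
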