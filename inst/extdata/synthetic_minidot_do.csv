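timestamp,do_mg_l
2023-07-01 00:00:00,6.868
2023-07-01 00:15:00,6.812
2023-07-01 00:30:00,6.91
2023-07-01 00:45:00,6.881
2023-07-01 01:00:00,6.861
2023-07-01 01:15:00,6.949
2023-07-01 01:30:00,7.024
2023-07-01 01:45:00,6.806
2023-07-01 02:00:00,7.03
2023-07-01 02:15:00,7.028
2023-07-01 02:30:00,6.8
2023-07-01 02:45:00,7.002
2023-07-01 03:00:00,6.975
2023-07-01 03:15:00,7.003
2023-07-01 03:30:00,6.873
2023-07-01 03:45:00,7.077
2023-07-01 04:00:00,7.275
2023-07-01 04:15:00,7.125
2023-07-01 04:30:00,7.082
2023-07-01 04:45:00,7.099
2023-07-01 05:00:00,7.162
2023-07-01 05:15:00,7.142
2023-07-01 05:30:00,6.982
2023-07-01 05:45:00,7.252
2023-07-01 06:00:00,7.259
2023-07-01 06:15:00,7.255
2023-07-01 06:30:00,7.431
2023-07-01 06:45:00,7.481
2023-07-01 07:00:00,7.598
2023-07-01 07:15:00,7.658
2023-07-01 07:30:00,7.736
2023-07-01 07:45:00,8.003
2023-07-01 08:00:00,8.01
2023-07-01 08:15:00,8.067
2023-07-01 08:30:00,8.603
2023-07-01 08:45:00,8.64
2023-07-01 09:00:00,8.719
2023-07-01 09:15:00,8.592
2023-07-01 09:30:00,8.923
2023-07-01 09:45:00,9.214
2023-07-01 10:00:00,9.196
2023-07-01 10:15:00,9.484
2023-07-01 10:30:00,9.358
2023-07-01 10:45:00,9.558
2023-07-01 11:00:00,9.626
2023-07-01 11:15:00,9.822
2023-07-01 11:30:00,9.829
2023-07-01 11:45:00,9.83
2023-07-01 12:00:00,9.854
2023-07-01 12:15:00,10.001
2023-07-01 12:30:00,10.059
2023-07-01 12:45:00,10.086
2023-07-01 13:00:00,10.066
2023-07-01 13:15:00,9.905
2023-07-01 13:30:00,10.014
2023-07-01 13:45:00,10.165
2023-07-01 14:00:00,10.073
2023-07-01 14:15:00,9.943
2023-07-01 14:30:00,9.946
2023-07-01 14:45:00,10.018
2023-07-01 15:00:00,9.843
2023-07-01 15:15:00,9.821
2023-07-01 15:30:00,9.629
2023-07-01 15:45:00,9.632
2023-07-01 16:00:00,9.61
2023-07-01 16:15:00,9.497
2023-07-01 16:30:00,9.488
2023-07-01 16:45:00,9.222
2023-07-01 17:00:00,8.999
2023-07-01 17:15:00,9.088
2023-07-01 17:30:00,8.584
2023-07-01 17:45:00,8.564
2023-07-01 18:00:00,8.402
2023-07-01 18:15:00,8.534
2023-07-01 18:30:00,8.356
2023-07-01 18:45:00,8.077
2023-07-01 19:00:00,7.913
2023-07-01 19:15:00,7.717
2023-07-01 19:30:00,7.676
2023-07-01 19:45:00,7.28
2023-07-01 20:00:00,7.27
2023-07-01 20:15:00,7.106
2023-07-01 20:30:00,7.173
2023-07-01 20:45:00,7.042
2023-07-01 21:00:00,7.113
2023-07-01 21:15:00,7.04
2023-07-01 21:30:00,6.976
2023-07-01 21:45:00,7.075
2023-07-01 22:00:00,6.809
2023-07-01 22:15:00,6.926
2023-07-01 22:30:00,6.931
2023-07-01 22:45:00,7.087
2023-07-01 23:00:00,7.053
2023-07-01 23:15:00,6.874
2023-07-01 23:30:00,6.998
2023-07-01 23:45:00,6.914
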