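timestamp,temp_c
2023-07-01 00:00:00,22.814
2023-07-01 00:15:00,22.702
2023-07-01 00:30:00,22.599
2023-07-01 00:45:00,22.503
2023-07-01 01:00:00,22.417
2023-07-01 01:15:00,22.34
2023-07-01 01:30:00,22.272
2023-07-01 01:45:00,22.215
2023-07-01 02:00:00,22.167
2023-07-01 02:15:00,22.13
2023-07-01 02:30:00,22.103
2023-07-01 02:45:00,22.087
2023-07-01 03:00:00,22.082
2023-07-01 03:15:00,22.087
2023-07-01 03:30:00,22.103
2023-07-01 03:45:00,22.13
2023-07-01 04:00:00,22.167
2023-07-01 04:15:00,22.215
2023-07-01 04:30:00,22.272
2023-07-01 04:45:00,22.34
2023-07-01 05:00:00,22.417
2023-07-01 05:15:00,22.503
2023-07-01 05:30:00,22.599
2023-07-01 05:45:00,22.702
2023-07-01 06:00:00,22.814
2023-07-01 06:15:00,22.934
2023-07-01 06:30:00,23.06
2023-07-01 06:45:00,23.193
2023-07-01 07:00:00,23.332
2023-07-01 07:15:00,23.476
2023-07-01 07:30:00,23.625
2023-07-01 07:45:00,23.778
2023-07-01 08:00:00,23.935
2023-07-01 08:15:00,24.094
2023-07-01 08:30:00,24.256
2023-07-01 08:45:00,24.418
2023-07-01 09:00:00,24.582
2023-07-01 09:15:00,24.745
2023-07-01 09:30:00,24.908
2023-07-01 09:45:00,25.07
2023-07-01 10:00:00,25.229
2023-07-01 10:15:00,25.386
2023-07-01 10:30:00,25.539
2023-07-01 10:45:00,25.688
2023-07-01 11:00:00,25.832
2023-07-01 11:15:00,25.971
2023-07-01 11:30:00,26.104
2023-07-01 11:45:00,26.23
2023-07-01 12:00:00,26.35
2023-07-01 12:15:00,26.462
2023-07-01 12:30:00,26.565
2023-07-01 12:45:00,26.661
2023-07-01 13:00:00,26.747
2023-07-01 13:15:00,26.824
2023-07-01 13:30:00,26.892
2023-07-01 13:45:00,26.949
2023-07-01 14:00:00,26.997
2023-07-01 14:15:00,27.034
2023-07-01 14:30:00,27.061
2023-07-01 14:45:00,27.077
2023-07-01 15:00:00,27.082
2023-07-01 15:15:00,27.077
2023-07-01 15:30:00,27.061
2023-07-01 15:45:00,27.034
2023-07-01 16:00:00,26.997
2023-07-01 16:15:00,26.949
2023-07-01 16:30:00,26.892
2023-07-01 16:45:00,26.824
2023-07-01 17:00:00,26.747
2023-07-01 17:15:00,26.661
2023-07-01 17:30:00,26.565
2023-07-01 17:45:00,26.462
2023-07-01 18:00:00,26.35
2023-07-01 18:15:00,26.23
2023-07-01 18:30:00,26.104
2023-07-01 18:45:00,25.971
2023-07-01 19:00:00,25.832
2023-07-01 19:15:00,25.688
2023-07-01 19:30:00,25.539
2023-07-01 19:45:00,25.386
2023-07-01 20:00:00,25.229
2023-07-01 20:15:00,25.07
2023-07-01 20:30:00,24.908
2023-07-01 20:45:00,24.745
2023-07-01 21:00:00,24.582
2023-07-01 21:15:00,24.418
2023-07-01 21:30:00,24.256
2023-07-01 21:45:00,24.094
2023-07-01 22:00:00,23.935
2023-07-01 22:15:00,23.778
2023-07-01 22:30:00,23.625
2023-07-01 22:45:00,23.476
2023-07-01 23:00:00,23.332
2023-07-01 23:15:00,23.193
2023-07-01 23:30:00,23.06
2023-07-01 23:45:00,22.934
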