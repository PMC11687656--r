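timestamp,lux
2023-07-01 00:00:00,0
2023-07-01 00:15:00,0
2023-07-01 00:30:00,0
2023-07-01 00:45:00,0
2023-07-01 01:00:00,0
2023-07-01 01:15:00,0
2023-07-01 01:30:00,0
2023-07-01 01:45:00,0
2023-07-01 02:00:00,0
2023-07-01 02:15:00,0
2023-07-01 02:30:00,0
2023-07-01 02:45:00,0
2023-07-01 03:00:00,0
2023-07-01 03:15:00,0
2023-07-01 03:30:00,0
2023-07-01 03:45:00,0
2023-07-01 04:00:00,0
2023-07-01 04:15:00,0
2023-07-01 04:30:00,0
2023-07-01 04:45:00,0
2023-07-01 05:00:00,0
2023-07-01 05:15:00,3730
2023-07-01 05:30:00,7449
2023-07-01 05:45:00,11144
2023-07-01 06:00:00,14804
2023-07-01 06:15:00,18418
2023-07-01 06:30:00,21973
2023-07-01 06:45:00,25459
2023-07-01 07:00:00,28866
2023-07-01 07:15:00,32181
2023-07-01 07:30:00,35395
2023-07-01 07:45:00,38498
2023-07-01 08:00:00,41480
2023-07-01 08:15:00,44331
2023-07-01 08:30:00,47043
2023-07-01 08:45:00,49607
2023-07-01 09:00:00,52014
2023-07-01 09:15:00,54258
2023-07-01 09:30:00,56331
2023-07-01 09:45:00,58227
2023-07-01 10:00:00,59940
2023-07-01 10:15:00,61464
2023-07-01 10:30:00,62795
2023-07-01 10:45:00,63929
2023-07-01 11:00:00,64861
2023-07-01 11:15:00,65589
2023-07-01 11:30:00,66110
2023-07-01 11:45:00,66424
2023-07-01 12:00:00,66529
2023-07-01 12:15:00,66424
2023-07-01 12:30:00,66110
2023-07-01 12:45:00,65589
2023-07-01 13:00:00,64861
2023-07-01 13:15:00,63929
2023-07-01 13:30:00,62795
2023-07-01 13:45:00,61464
2023-07-01 14:00:00,59940
2023-07-01 14:15:00,58227
2023-07-01 14:30:00,56331
2023-07-01 14:45:00,54258
2023-07-01 15:00:00,52014
2023-07-01 15:15:00,49607
2023-07-01 15:30:00,47043
2023-07-01 15:45:00,44331
2023-07-01 16:00:00,41480
2023-07-01 16:15:00,38498
2023-07-01 16:30:00,35395
2023-07-01 16:45:00,32181
2023-07-01 17:00:00,28866
2023-07-01 17:15:00,25459
2023-07-01 17:30:00,21973
2023-07-01 17:45:00,18418
2023-07-01 18:00:00,14804
2023-07-01 18:15:00,11144
2023-07-01 18:30:00,7449
2023-07-01 18:45:00,3730
2023-07-01 19:00:00,0
2023-07-01 19:15:00,0
2023-07-01 19:30:00,0
2023-07-01 19:45:00,0
2023-07-01 20:00:00,0
2023-07-01 20:15:00,0
2023-07-01 20:30:00,0
2023-07-01 20:45:00,0
2023-07-01 21:00:00,0
2023-07-01 21:15:00,0
2023-07-01 21:30:00,0
2023-07-01 21:45:00,0
2023-07-01 22:00:00,0
2023-07-01 22:15:00,0
2023-07-01 22:30:00,0
2023-07-01 22:45:00,0
2023-07-01 23:00:00,0
2023-07-01 23:15:00,0
2023-07-01 23:30:00,0
2023-07-01 23:45:00,0
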