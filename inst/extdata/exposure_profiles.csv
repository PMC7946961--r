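profile,day_class,start,end
workaholic,weekday,06:55,07:00
workaholic,weekday,19:00,19:05
office_int_lunch,weekday,07:45,08:00
office_int_lunch,weekday,17:15,17:30
office_ext_lunch,weekday,12:25,12:35
office_ext_lunch_free_time,weekday,12:25,12:35
office_ext_lunch_free_time,weekday,18:00,19:00
outside_worker,weekday,08:00,12:00
outside_worker,weekday,13:30,14:00
active_weekend,weekend,10:00,12:00
active_weekend,weekend,13:00,15:30
passive_weekend,weekend,12:00,12:05
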