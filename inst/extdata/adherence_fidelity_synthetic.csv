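participant_id,attended_education,calls_completed,wk1,wk2,wk3,wk4,wk5,wk6,wk7,wk8,wk9,wk10,wk11,wk12
S001,1,4,7,5,6,5,7,6,7,5,7,7,5,5
S002,1,3,6,5,7,7,6,5,6,6,7,6,5,5
S003,1,4,6,5,5,5,7,6,7,6,5,7,5,7
S004,1,4,6,6,5,6,5,6,6,5,5,5,5,7
S005,1,4,6,5,5,7,7,5,5,7,6,7,5,6
S006,1,3,6,6,7,7,7,6,5,6,7,7,5,7
S007,1,3,6,5,5,5,5,5,5,5,6,5,5,6
S008,1,3,5,7,6,7,5,5,7,7,6,7,6,6
S009,1,3,7,6,6,7,7,7,5,5,7,5,7,6
S010,1,4,7,7,7,6,7,6,6,5,5,6,5,7
S011,1,3,5,7,6,7,6,6,5,5,6,7,6,6
S012,1,4,6,5,5,6,6,5,6,6,6,7,6,7
S013,1,3,5,7,5,5,6,6,5,5,5,5,7,6
S014,1,3,6,7,6,7,6,5,7,6,7,7,7,7
S015,1,4,6,5,5,7,5,5,5,6,7,5,6,5
S016,1,4,6,5,5,7,5,7,6,6,7,6,6,7
S017,1,4,6,6,6,6,7,7,7,6,6,7,5,7
S018,1,4,7,5,6,5,5,6,5,7,6,6,6,5
S019,1,4,6,6,6,5,7,7,6,7,6,6,5,7
S020,1,4,5,7,6,6,7,6,6,5,5,7,7,5
S021,1,3,7,7,6,7,6,5,7,7,5,7,7,6
S022,1,4,6,5,5,5,7,5,5,5,6,6,3,0
S023,1,4,7,6,5,7,7,7,2,7,1,6,5,6
S024,1,3,0,7,6,6,6,6,7,2,5,6,5,7
S025,1,3,7,6,5,6,0,7,6,1,6,7,6,7
S026,1,2,7,6,7,7,7,4,6,6,7,5,5,1
S027,1,3,6,7,7,7,5,7,5,5,7,6,7,7
S028,1,3,5,6,6,5,6,6,7,5,6,6,7,6
S029,1,4,5,6,6,7,5,6,5,7,7,5,7,7
S030,1,4,7,5,7,5,6,7,6,5,7,5,5,7
S031,1,4,5,6,6,6,7,7,7,6,6,7,6,6
S032,1,3,7,7,5,5,6,6,7,6,5,5,7,5
S033,1,3,5,7,6,6,6,6,7,5,5,7,7,5
S034,1,3,7,6,5,5,6,6,6,7,6,7,5,7
S035,1,4,6,6,6,7,5,5,5,5,5,6,5,5
S036,1,4,5,7,6,5,5,5,5,7,5,5,6,7
S037,1,4,7,5,5,6,7,5,6,7,6,5,5,5
S038,1,4,6,5,6,5,6,7,6,5,7,6,6,6
S039,1,4,5,5,7,7,6,5,5,6,5,6,6,6
S040,1,3,7,5,7,5,6,7,6,7,7,6,5,6
S041,1,4,7,7,5,6,7,5,6,6,6,6,5,7
S042,1,3,6,6,5,6,5,6,7,6,6,5,5,5
S043,1,3,5,5,6,7,6,5,7,6,5,5,6,5
S044,1,3,7,5,7,7,5,5,7,5,5,7,5,6
S045,1,3,6,6,7,3,5,5,6,0,5,7,7,7
S046,1,3,6,7,5,5,3,5,5,5,2,7,6,6
S047,1,4,7,0,5,6,5,5,7,7,7,5,6,1
S048,1,3,5,4,6,7,7,6,5,5,5,2,5,5
S049,1,2,5,7,7,6,5,6,5,5,5,5,5,7
S050,1,2,7,5,5,7,7,7,7,6,5,6,5,5
S051,1,1,5,7,7,6,6,5,6,6,6,0,1,5
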