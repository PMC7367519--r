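participant_id,arm,block_id
S001,IG,1
S002,IG,1
S003,IG,1
S004,IG,1
S005,IG,2
S006,IG,2
S007,IG,2
S008,IG,2
S009,IG,3
S010,IG,3
S011,IG,3
S012,IG,3
S013,IG,4
S014,IG,4
S015,IG,4
S016,IG,4
S017,IG,5
S018,IG,5
S019,IG,5
S020,IG,5
S021,IG,6
S022,IG,6
S023,IG,6
S024,IG,6
S025,IG,7
S026,IG,7
S027,DG,7
S028,DG,7
S029,DG,8
S030,DG,8
S031,DG,8
S032,DG,8
S033,DG,9
S034,DG,9
S035,DG,9
S036,DG,9
S037,DG,10
S038,DG,10
S039,DG,10
S040,DG,10
S041,DG,11
S042,DG,11
S043,DG,11
S044,DG,11
S045,DG,12
S046,DG,12
S047,DG,12
S048,DG,12
S049,DG,13
S050,DG,13
S051,DG,13
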