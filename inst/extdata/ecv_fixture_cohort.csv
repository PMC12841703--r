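id,parity,presentation,engaged,palpable_head,efw_ge_10th,mvp_ge_4cm,placenta_posterior,tocolysis,success
p001,multiparous,transverse,0,1,1,1,1,1,1
p002,multiparous,transverse,0,1,1,1,1,1,1
p003,multiparous,transverse,0,1,1,1,1,1,1
p004,multiparous,transverse,0,1,1,1,1,1,1
p005,multiparous,transverse,0,1,1,1,1,1,1
p006,multiparous,transverse,0,1,1,1,1,1,1
p007,multiparous,transverse,0,1,1,1,1,1,1
p008,multiparous,complete_breech,1,1,1,1,1,1,1
p009,multiparous,complete_breech,1,1,1,1,1,1,1
p010,multiparous,complete_breech,1,1,1,1,1,1,1
p011,multiparous,complete_breech,1,1,1,1,1,1,1
p012,multiparous,complete_breech,1,1,1,1,1,1,1
p013,multiparous,complete_breech,1,1,1,1,1,1,1
p014,multiparous,complete_breech,1,1,1,1,1,1,1
p015,multiparous,complete_breech,1,1,1,1,1,1,1
p016,multiparous,complete_breech,1,1,1,1,1,1,1
p017,multiparous,complete_breech,1,1,1,1,1,1,1
p018,multiparous,complete_breech,1,1,1,1,1,1,1
p019,multiparous,frank_breech,1,1,1,1,1,1,1
p020,multiparous,frank_breech,1,1,1,1,1,1,1
p021,multiparous,frank_breech,1,1,1,1,1,1,1
p022,multiparous,frank_breech,1,1,1,1,1,1,1
p023,multiparous,frank_breech,1,1,1,1,1,1,1
p024,multiparous,frank_breech,1,1,1,1,1,1,1
p025,multiparous,frank_breech,1,1,1,1,1,1,1
p026,multiparous,frank_breech,1,1,1,1,1,1,1
p027,multiparous,frank_breech,1,1,1,1,1,1,1
p028,multiparous,frank_breech,1,1,1,1,1,1,1
p029,multiparous,frank_breech,1,1,1,1,1,1,1
p030,multiparous,frank_breech,1,1,1,1,1,1,1
p031,multiparous,frank_breech,1,1,1,1,1,1,1
p032,multiparous,frank_breech,1,1,1,1,1,1,1
p033,multiparous,frank_breech,1,1,1,1,1,1,1
p034,multiparous,frank_breech,1,1,1,1,1,1,1
p035,multiparous,frank_breech,1,1,1,1,1,1,1
p036,multiparous,frank_breech,1,1,1,1,1,1,1
p037,multiparous,frank_breech,1,1,1,1,1,1,1
p038,multiparous,frank_breech,1,1,1,1,1,1,1
p039,multiparous,frank_breech,1,1,1,1,1,1,1
p040,multiparous,frank_breech,1,1,1,1,1,1,1
p041,multiparous,frank_breech,1,1,1,1,1,1,1
p042,multiparous,frank_breech,1,1,1,1,1,1,1
p043,nulliparous,frank_breech,1,1,1,1,1,1,1
p044,nulliparous,frank_breech,1,1,1,1,0,1,1
p045,nulliparous,frank_breech,1,1,1,1,0,1,1
p046,nulliparous,frank_breech,1,1,1,1,0,0,1
p047,nulliparous,frank_breech,1,1,1,1,0,0,1
p048,nulliparous,frank_breech,1,1,1,1,0,0,1
p049,nulliparous,frank_breech,1,1,1,1,0,0,1
p050,nulliparous,frank_breech,1,1,1,1,0,0,1
p051,nulliparous,frank_breech,1,1,1,1,0,0,1
p052,nulliparous,frank_breech,1,1,1,1,0,0,1
p053,nulliparous,frank_breech,1,1,1,1,0,0,1
p054,nulliparous,frank_breech,1,1,1,1,0,0,1
p055,nulliparous,frank_breech,1,1,1,1,0,0,1
p056,nulliparous,frank_breech,1,1,0,1,0,0,1
p057,nulliparous,frank_breech,1,1,0,1,0,0,1
p058,nulliparous,frank_breech,1,1,0,1,0,0,1
p059,nulliparous,frank_breech,1,1,0,1,0,0,1
p060,nulliparous,frank_breech,1,1,0,1,0,0,1
p061,nulliparous,frank_breech,1,1,0,1,0,0,1
p062,nulliparous,frank_breech,1,1,0,1,0,0,1
p063,nulliparous,frank_breech,1,1,0,1,0,0,1
p064,nulliparous,frank_breech,1,0,0,1,0,0,1
p065,nulliparous,frank_breech,1,0,0,1,0,0,1
p066,nulliparous,frank_breech,1,0,0,1,0,0,1
p067,nulliparous,frank_breech,1,0,0,1,0,0,1
p068,nulliparous,frank_breech,1,0,0,0,0,0,1
p069,nulliparous,frank_breech,1,0,0,0,0,0,1
p070,multiparous,transverse,0,1,1,1,1,1,0
p071,multiparous,complete_breech,0,1,1,1,1,1,0
p072,multiparous,complete_breech,0,1,1,1,1,1,0
p073,multiparous,complete_breech,0,1,1,1,1,1,0
p074,multiparous,complete_breech,0,1,1,1,1,1,0
p075,multiparous,complete_breech,0,1,1,1,1,1,0
p076,multiparous,frank_breech,0,0,1,1,0,1,0
p077,multiparous,frank_breech,0,0,1,1,0,1,0
p078,multiparous,frank_breech,0,0,1,1,0,1,0
p079,multiparous,frank_breech,0,0,1,1,0,1,0
p080,multiparous,frank_breech,0,0,1,1,0,1,0
p081,multiparous,frank_breech,0,0,1,1,0,1,0
p082,multiparous,frank_breech,0,0,1,1,0,1,0
p083,nulliparous,frank_breech,0,0,1,1,0,1,0
p084,nulliparous,frank_breech,0,0,1,1,0,1,0
p085,nulliparous,frank_breech,0,0,1,1,0,1,0
p086,nulliparous,frank_breech,0,0,1,1,0,1,0
p087,nulliparous,frank_breech,0,0,1,1,0,1,0
p088,nulliparous,frank_breech,0,0,1,1,0,1,0
p089,nulliparous,frank_breech,0,0,1,0,0,1,0
p090,nulliparous,frank_breech,0,0,1,0,0,0,0
p091,nulliparous,frank_breech,0,0,1,0,0,0,0
p092,nulliparous,frank_breech,0,0,1,0,0,0,0
p093,nulliparous,frank_breech,0,0,1,0,0,0,0
p094,nulliparous,frank_breech,0,0,1,0,0,0,0
p095,nulliparous,frank_breech,0,0,0,0,0,0,0
p096,nulliparous,frank_breech,0,0,0,0,0,0,0
p097,nulliparous,frank_breech,0,0,0,0,0,0,0
p098,nulliparous,frank_breech,0,0,0,0,0,0,0
p099,nulliparous,frank_breech,1,0,0,0,0,0,0
p100,nulliparous,frank_breech,1,0,0,0,0,0,0
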