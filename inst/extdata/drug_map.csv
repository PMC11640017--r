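hcpcs_code,drug_class
J9000,chemotherapy
J9001,chemotherapy
J9002,chemotherapy
J9003,chemotherapy
J9004,chemotherapy
J9005,chemotherapy
J9006,chemotherapy
J9007,chemotherapy
J9008,chemotherapy
J9009,chemotherapy
J9010,chemotherapy
J9011,chemotherapy
J9012,chemotherapy
J9013,chemotherapy
J9014,chemotherapy
J9015,chemotherapy
J9016,chemotherapy
J9017,chemotherapy
J9018,chemotherapy
J9019,chemotherapy
J9020,chemotherapy
J9021,chemotherapy
J9022,chemotherapy
J9023,chemotherapy
J9024,chemotherapy
J9025,chemotherapy
J9026,chemotherapy
J9027,chemotherapy
J9028,chemotherapy
J9029,chemotherapy
J9030,chemotherapy
J9031,chemotherapy
J9032,chemotherapy
J9033,chemotherapy
J9034,chemotherapy
J9035,chemotherapy
J9036,chemotherapy
J9037,chemotherapy
J9038,chemotherapy
J9039,chemotherapy
J9040,chemotherapy
J9041,chemotherapy
J9042,chemotherapy
J9043,chemotherapy
J9044,chemotherapy
J9045,chemotherapy
J9046,chemotherapy
J9047,chemotherapy
J9048,chemotherapy
J9049,chemotherapy
J9050,chemotherapy
J9051,chemotherapy
J9052,chemotherapy
J9053,chemotherapy
J9054,chemotherapy
J9055,chemotherapy
J9056,chemotherapy
J9057,chemotherapy
J9058,chemotherapy
J9059,chemotherapy
J9060,chemotherapy
J9061,chemotherapy
J9062,chemotherapy
J9063,chemotherapy
J9064,chemotherapy
J9065,chemotherapy
J9066,chemotherapy
J9067,chemotherapy
J9068,chemotherapy
J9069,chemotherapy
J9070,chemotherapy
J9071,chemotherapy
J9072,chemotherapy
J9073,chemotherapy
J9074,chemotherapy
J9075,chemotherapy
J9076,chemotherapy
J9077,chemotherapy
J9078,chemotherapy
J9079,chemotherapy
J9080,chemotherapy
J9081,chemotherapy
J9200,biotherapy
J9201,biotherapy
J9202,biotherapy
J9203,biotherapy
J9204,biotherapy
J9205,biotherapy
J9206,biotherapy
J9207,biotherapy
J9208,biotherapy
J9209,biotherapy
J9210,biotherapy
J9211,biotherapy
J9212,biotherapy
J9213,biotherapy
J9214,biotherapy
J9215,biotherapy
J9216,biotherapy
J9217,biotherapy
J9218,biotherapy
J9219,biotherapy
J9220,biotherapy
J9221,biotherapy
J9222,biotherapy
J9223,biotherapy
J9224,biotherapy
J9225,biotherapy
J9226,biotherapy
J9227,biotherapy
J9228,biotherapy
J9229,biotherapy
J9230,biotherapy
J9231,biotherapy
J9232,biotherapy
J9233,biotherapy
J9234,biotherapy
J9235,biotherapy
J9236,biotherapy
J9237,biotherapy
J9238,biotherapy
J9239,biotherapy
J9240,biotherapy
J9241,biotherapy
J9242,biotherapy
J9243,biotherapy
J9244,biotherapy
J9245,biotherapy
J9246,biotherapy
J9247,biotherapy
J9248,biotherapy
J9300,hormone
J9301,hormone
J9302,hormone
J9303,hormone
J9304,hormone
J9305,hormone
J9306,hormone
J9307,hormone
J9308,hormone
J9309,hormone
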