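genotype table export
loc01
loc02
loc03
loc04
loc05
pop
ind_001 , 002002 002002 001005 005006 001003
ind_002 , 002002 002002 003007 005004 001001
ind_003 , 002005 005001 004008 004002 001001
ind_004 , 002002 002006 008004 005002 005005
ind_005 , 002005 001002 007005 004005 002001
ind_006 , 002001 005006 007003 005006 001001
ind_007 , 002002 006005 008004 005005 004005
ind_008 , 002002 005006 002004 005001 003001
pop
ind_009 , 002001 005002 008008 005005 005003
ind_010 , 002002 006006 003007 005005 002003
ind_011 , 004002 002003 003008 005006 003001
ind_012 , 002005 002002 003007 005001 001004
ind_013 , 003002 005005 003007 005005 001005
ind_014 , 002006 005002 005003 005001 001001
ind_015 , 002002 005003 007007 002002 001001
ind_016 , 006002 002006 003007 001005 004001
pop
ind_017 , 006006 005003 001003 005008 001003
ind_018 , 005006 002006 004007 008001 001003
ind_019 , 002002 006005 007008 008002 002002
ind_020 , 002002 003005 001008 005001 001005
ind_021 , 006002 002003 007007 006004 001001
ind_022 , 005004 006003 008008 004001 004004
ind_023 , 002002 006003 006008 006005 005005
ind_024 , 002002 005003 001001 001008 001002
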