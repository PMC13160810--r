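label,conflict_type,indicators,improving_id,improving,worsening_id,worsening,principles
Emergency power supply,physical,A1;D2,NA,Power reliability,NA,Equipment energy consumption and storage pressure,3 17 31 40
Information sharing and privacy protection,physical,A5;D5,NA,Information integrity,NA,Information leak,19 31 32
Functional integration and spatial accessibility,technical,B3;A4,34,Practicality (age-friendly),36,System complexity,
Intelligent automation and user control,technical,B4;C1,43,Automation level,37,System security,
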