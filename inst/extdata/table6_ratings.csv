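fm_id,expert_id,occurrence,severity,detection
FM1,panel,Very High,Dangerous without warning,Low
FM2,panel,Moderate,very high,Moderate
FM3,panel,Moderate,very high,Moderate
FM4,panel,Low,Dangerous with warnings,Moderate
FM5,panel,High,high,Moderate
FM6,panel,High,very high,Low
FM7,panel,Remote,high,Moderate
FM8,panel,High,high,Very Low
FM9,panel,High,high,Very Low
FM10,panel,Moderate,high,Low
FM11,panel,,,
FM12,panel,,,
FM13,panel,,,
FM14,panel,,,
FM15,panel,,,
FM16,panel,,,
FM17,panel,,,
FM18,panel,,,
FM19,panel,,,
FM20,panel,,,
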