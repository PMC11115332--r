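{"occurrence":[{"label":"Remote","tfn":[1,2,3],"description":"Failure unlikely"},{"label":"Very Remote","tfn":[2,3,4],"description":"Rare failures"},{"label":"Very Low","tfn":[3,4,5],"description":"Isolated failures"},{"label":"Low","tfn":[4,5,6],"description":"Relatively few failures"},{"label":"Moderately Low","tfn":[5,6,7],"description":"Occasional failures"},{"label":"Moderate","tfn":[6,7,8],"description":"Moderately frequent"},{"label":"Moderately High","tfn":[7,8,9],"description":"Frequent failures"},{"label":"High","tfn":[8,9,10],"description":"Repeated failures"},{"label":"Very High","tfn":[9,10,10],"description":"Failure almost inevitable"}],"severity":[{"label":"Very minor","tfn":[1,2,3],"description":"Natural function with minor effects"},{"label":"minor","tfn":[2,3,4],"description":"Normal performance with slight reduction"},{"label":"very Low","tfn":[3,4,5],"description":"Normal performance with reduced capability"},{"label":"Low","tfn":[4,5,6],"description":"Abnormal performance with little impact"},{"label":"Moderate","tfn":[5,6,7],"description":"Abnormal and repairable performance"},{"label":"high","tfn":[6,7,8],"description":"Abnormal performance"},{"label":"very high","tfn":[7,8,9],"description":"Destructive changes"},{"label":"Dangerous with warnings","tfn":[8,9,10],"description":"Extremely high event intensity with alert"},{"label":"Dangerous without warning","tfn":[9,10,10],"description":"Extreme intensity without warning"}],"detection":[{"label":"Very High","tfn":[1,1,3],"description":"Chance of discovery is very high"},{"label":"High","tfn":[1,3,5],"description":"High chance of discovery"},{"label":"Moderate","tfn":[3,5,7],"description":"Probability so-so"},{"label":"Low","tfn":[5,7,9],"description":"Low chance by experiment"},{"label":"Very Low","tfn":[8,10,10],"description":"Very low chance of discovery"},{"label":"Remote","tfn":[8,10,10],"description":"No chance to discover"}],"rpn_output":[{"label":"VL","tfn":[0,0,0.25],"description":"Very Low"},{"label":"L","tfn":[0,0.25,0.5],"description":"Low"},{"label":"M","tfn":[0.25,0.5,0.75],"description":"Moderate"},{"label":"H","tfn":[0.5,0.75,1],"description":"High"},{"label":"VH","tfn":[0.75,1,1],"description":"Very High"}]}
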