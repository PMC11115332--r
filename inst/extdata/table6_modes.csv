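fm_id,description,cause,effect,ffmea_label,ffmea_crisp
FM1,Irregular consumption of immunosuppressive drugs,Failure and negligence on the part of the recipient to follow medical advice,Rejection of transplant / reduced quality of transplanted organ,VH,0.930
FM2,Possibility of post-transplant diseases,Taking anti-transplant rejection drugs (immunosuppressants),Rejection / reduced organ quality / death of the recipient,VH,0.911
FM3,Ignoring post-transplant quarantine rules,Failure and negligence on the part of the recipient to follow medical advice,Rejection of transplant / reduced quality of transplanted organ,VH,0.911
FM4,Error in medical research before transplantation,Negligence of the laboratory and the transplant team,Rejection / reduced organ quality / death of the recipient,H,0.750
FM5,Donor creatinine levels,"Decreased blood flow, dehydration, diet",Rejection / reduced organ quality / death of the recipient,H,0.750
FM6,Elapsed ischemic time of the transplanted organ,Mismanagement planning and type of organ allocation in network,Rejection / reduced organ quality / death of the recipient,VH,0.750
FM7,Heavy work after transplantation,Failure and negligence on the part of the recipient to follow medical advice,Rejection of transplant / reduced quality of transplanted organ,H,0.750
FM8,Mental illness,Patients' conscience agony,Rejection of transplant / reduced quality of transplanted organ,H,0.750
FM9,Improper diet,Failure and negligence on the part of the recipient to follow medical advice,Rejection of transplant / reduced quality of transplanted organ,H,0.750
FM10,Possibility of oral diseases,Taking anti-transplant rejection drugs (immunosuppressants),,L,0.500
FM11,Exposure to harmful sunlight or radiation (skin cancer),,,,
FM12,Cytomegalovirus infection after transplantation,,,,
FM13,Contracting other viral infections,,,,
FM14,Excessive weight gain,,,,
FM15,Medical errors in surgery or post-operative care,,,,
FM16,Pregnancy after organ transplantation,,,,
FM17,Organ storage duration and tissue deterioration,,,,
FM18,Donor-recipient age compatibility,,,,
FM19,Compromised physical function after transplantation,,,,
FM20,Insufficient physical activity and restricted mobility,,,,
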