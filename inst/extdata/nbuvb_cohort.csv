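patient_id,sex,age,ethnicity,hair_colour,eye_colour,darkest_tan,freckling,prior_phototherapy,prior_phototherapy_type,med_sed,med_jcm2,n_exposures,total_dose_sed,site,burden_pre,burden_post,days_to_second_biopsy
1,M,26,White Irish,Light brown,Blue/blue,Light golden,TRUE,FALSE,,2.9,0.5,33,165,buttock,0.072,0.685,34
2,M,37,Asian other,Black,Brown/brown,Dark brown,FALSE,FALSE,,5.1,0.9,30,756,buttock,0.098,0.26,11
3,F,30,White British,Light brown,Grey/green,Medium brown,TRUE,TRUE,UVB,1.7,0.3,23,151,buttock,0.575,1.576,28
4,M,50,Asian Indian,Black,Tan/brown,Dark brown,FALSE,TRUE,UVB,4,0.7,14,84,buttock,0.195,0.225,82
6,F,20,White British,Ash brown,Yellow/tan,Medium brown,FALSE,TRUE,NB-UVB,2.9,0.5,28,183,buttock,0.434,0.799,13
7,F,24,White British,Medium brown,Blue/grey,Light golden,FALSE,FALSE,,2.3,0.4,35,375,buttock,0.081,0.853,10
8,M,73,White British,Ash blonde,Grey/tan,Medium brown,FALSE,TRUE,"PUVA, NB-UVB",1.7,0.3,29,237,buttock,1.174,1.613,22
10,M,55,White British,Medium brown,Grey/green,Dark brown,FALSE,TRUE,NB-UVB,2.9,0.5,28,427,buttock,0.83,1.219,22
11,F,26,White British,Light brown,Blue/grey,Light golden,FALSE,FALSE,,1.7,0.3,34,217,buttock,0.207,0.679,14
12,M,32,White British,Dark brown,Tan/brown,Light golden,TRUE,TRUE,NB-UVB,2.9,0.5,30,192,buttock,0.801,1.622,61
15,F,59,White British,Dark brown,Grey/blue,Medium brown,TRUE,TRUE,NB-UVB,1.7,0.3,26,219,buttock,2.74,3.599,105
17,M,52,White British,Dark brown,Brown/brown,Dark brown,TRUE,TRUE,NB-UVB,1.7,0.3,35,529,buttock,1.478,2.191,105
18,F,34,White British,Dark brown,Grey/tan,Medium brown,FALSE,TRUE,NB-UVB,1.7,0.3,28,224,buttock,1.065,1.836,98
19,M,26,White British,Ash blonde,Green/tan,Light golden,TRUE,TRUE,type unknown,2.9,0.5,28,419,buttock,0.47,0.966,12
6,F,20,White British,Ash brown,Yellow/tan,Medium brown,FALSE,TRUE,NB-UVB,2.9,0.5,28,183,forearm,0.95,2.217,13
7,F,24,White British,Medium brown,Blue/grey,Light golden,FALSE,FALSE,,2.3,0.4,35,375,forearm,1.996,2.584,10
8,M,73,White British,Ash blonde,Grey/tan,Medium brown,FALSE,TRUE,"PUVA, NB-UVB",1.7,0.3,29,237,forearm,5.199,6.681,22
10,M,55,White British,Medium brown,Grey/green,Dark brown,FALSE,TRUE,NB-UVB,2.9,0.5,28,427,forearm,4.069,5.198,22
11,F,26,White British,Light brown,Blue/grey,Light golden,FALSE,FALSE,,1.7,0.3,34,217,forearm,2.547,2.372,14
12,M,32,White British,Dark brown,Tan/brown,Light golden,TRUE,TRUE,NB-UVB,2.9,0.5,30,192,forearm,4.967,5.793,61
14,M,60,White British,Dark brown,Grey/green,Dark brown,FALSE,FALSE,,5.1,0.9,21,128,forearm,2.337,2.337,7
17,M,52,White British,Dark brown,Brown/brown,Dark brown,TRUE,TRUE,NB-UVB,1.7,0.3,35,529,forearm,7.498,10.591,105
18,F,34,White British,Dark brown,Grey/tan,Medium brown,FALSE,TRUE,NB-UVB,1.7,0.3,28,224,forearm,3.578,4.524,98
19,M,26,White British,Ash blonde,Green/tan,Light golden,TRUE,TRUE,type unknown,2.9,0.5,28,419,forearm,2.688,3.024,12
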