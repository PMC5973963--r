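ID,STUDY,TIME,AMT,EVID,DV,MDV,BLQ,FORM,AGE,WT,SEX,RACE,POP,DOSE
demo-1,demo,0,20,1,,1,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,0,,0,,1,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,1,,0,4.29660116753967,0,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,2,,0,19.2944015819125,0,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,4,,0,37.8634668244021,0,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,8,,0,18.6799844697058,0,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,24,,0,43.4964296686783,0,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,168,,0,7.68075528784666,0,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,336,,0,2.19972161770393,0,0,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-1,demo,504,,0,0.403853368753714,1,1,tablet,49.1600951599733,78.8003856991635,female,White,HV,20
demo-2,demo,0,20,1,,1,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,0,,0,,1,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,1,,0,4.33400213012051,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,2,,0,16.0094096309674,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,4,,0,24.6939188957153,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,8,,0,24.8246665956324,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,24,,0,29.772436369621,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,168,,0,17.080120921742,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,336,,0,3.49201592346148,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-2,demo,504,,0,1.50377747372833,0,0,tablet,35.4070184580813,86.3956610886289,male,White,HV,20
demo-3,demo,0,20,1,,1,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,0,,0,,1,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,1,,0,92.9585865477812,0,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,2,,0,55.5826243296417,0,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,4,,0,70.6307987503306,0,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,8,,0,54.7055550032514,0,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,24,,0,57.3809656252795,0,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,168,,0,15.0666251309755,0,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,336,,0,3.96932200237781,0,0,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-3,demo,504,,0,0.283270449856843,1,1,tablet,44.3806115664525,77.5515122365062,female,White,HV,20
demo-4,demo,0,20,1,,1,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,0,,0,,1,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,1,,0,43.3318104157238,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,2,,0,98.7013663157762,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,4,,0,93.4556842049255,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,8,,0,44.9496680763989,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,24,,0,82.4272617875663,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,168,,0,21.6040094274993,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,336,,0,10.9258864551695,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
demo-4,demo,504,,0,2.53140776649527,0,0,tablet,44.8591427774662,73.9613964795003,female,White,HV,20
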