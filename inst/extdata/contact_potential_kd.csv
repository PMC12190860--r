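# Synthetic hydrophobic contact potential (kcal/mol), derived from the
# Kyte-Doolittle hydropathy scale: e(a,b) = -h(a)*h(b) with h rescaled to [0,1].
"","A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"
"A",-0.49,-0.544444,-0.077778,-0.077778,-0.567778,-0.318889,-0.101111,-0.7,-0.046667,-0.645556,-0.497778,-0.077778,-0.225556,-0.077778,0,-0.287778,-0.295556,-0.676667,-0.28,-0.248889
"C",-0.544444,-0.604938,-0.08642,-0.08642,-0.630864,-0.354321,-0.112346,-0.777778,-0.051852,-0.717284,-0.553086,-0.08642,-0.250617,-0.08642,0,-0.319753,-0.328395,-0.751852,-0.311111,-0.276543
"D",-0.077778,-0.08642,-0.012346,-0.012346,-0.090123,-0.050617,-0.016049,-0.111111,-0.007407,-0.102469,-0.079012,-0.012346,-0.035802,-0.012346,0,-0.045679,-0.046914,-0.107407,-0.044444,-0.039506
"E",-0.077778,-0.08642,-0.012346,-0.012346,-0.090123,-0.050617,-0.016049,-0.111111,-0.007407,-0.102469,-0.079012,-0.012346,-0.035802,-0.012346,0,-0.045679,-0.046914,-0.107407,-0.044444,-0.039506
"F",-0.567778,-0.630864,-0.090123,-0.090123,-0.657901,-0.369506,-0.11716,-0.811111,-0.054074,-0.748025,-0.57679,-0.090123,-0.261358,-0.090123,0,-0.333457,-0.342469,-0.784074,-0.324444,-0.288395
"G",-0.318889,-0.354321,-0.050617,-0.050617,-0.369506,-0.207531,-0.065802,-0.455556,-0.03037,-0.420123,-0.323951,-0.050617,-0.14679,-0.050617,0,-0.187284,-0.192346,-0.44037,-0.182222,-0.161975
"H",-0.101111,-0.112346,-0.016049,-0.016049,-0.11716,-0.065802,-0.020864,-0.144444,-0.00963,-0.13321,-0.102716,-0.016049,-0.046543,-0.016049,0,-0.059383,-0.060988,-0.13963,-0.057778,-0.051358
"I",-0.7,-0.777778,-0.111111,-0.111111,-0.811111,-0.455556,-0.144444,-1,-0.066667,-0.922222,-0.711111,-0.111111,-0.322222,-0.111111,0,-0.411111,-0.422222,-0.966667,-0.4,-0.355556
"K",-0.046667,-0.051852,-0.007407,-0.007407,-0.054074,-0.03037,-0.00963,-0.066667,-0.004444,-0.061481,-0.047407,-0.007407,-0.021481,-0.007407,0,-0.027407,-0.028148,-0.064444,-0.026667,-0.023704
"L",-0.645556,-0.717284,-0.102469,-0.102469,-0.748025,-0.420123,-0.13321,-0.922222,-0.061481,-0.850494,-0.655802,-0.102469,-0.29716,-0.102469,0,-0.379136,-0.389383,-0.891481,-0.368889,-0.327901
"M",-0.497778,-0.553086,-0.079012,-0.079012,-0.57679,-0.323951,-0.102716,-0.711111,-0.047407,-0.655802,-0.505679,-0.079012,-0.229136,-0.079012,0,-0.292346,-0.300247,-0.687407,-0.284444,-0.25284
"N",-0.077778,-0.08642,-0.012346,-0.012346,-0.090123,-0.050617,-0.016049,-0.111111,-0.007407,-0.102469,-0.079012,-0.012346,-0.035802,-0.012346,0,-0.045679,-0.046914,-0.107407,-0.044444,-0.039506
"P",-0.225556,-0.250617,-0.035802,-0.035802,-0.261358,-0.14679,-0.046543,-0.322222,-0.021481,-0.29716,-0.229136,-0.035802,-0.103827,-0.035802,0,-0.132469,-0.136049,-0.311481,-0.128889,-0.114568
"Q",-0.077778,-0.08642,-0.012346,-0.012346,-0.090123,-0.050617,-0.016049,-0.111111,-0.007407,-0.102469,-0.079012,-0.012346,-0.035802,-0.012346,0,-0.045679,-0.046914,-0.107407,-0.044444,-0.039506
"R",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"S",-0.287778,-0.319753,-0.045679,-0.045679,-0.333457,-0.187284,-0.059383,-0.411111,-0.027407,-0.379136,-0.292346,-0.045679,-0.132469,-0.045679,0,-0.169012,-0.17358,-0.397407,-0.164444,-0.146173
"T",-0.295556,-0.328395,-0.046914,-0.046914,-0.342469,-0.192346,-0.060988,-0.422222,-0.028148,-0.389383,-0.300247,-0.046914,-0.136049,-0.046914,0,-0.17358,-0.178272,-0.408148,-0.168889,-0.150123
"V",-0.676667,-0.751852,-0.107407,-0.107407,-0.784074,-0.44037,-0.13963,-0.966667,-0.064444,-0.891481,-0.687407,-0.107407,-0.311481,-0.107407,0,-0.397407,-0.408148,-0.934444,-0.386667,-0.343704
"W",-0.28,-0.311111,-0.044444,-0.044444,-0.324444,-0.182222,-0.057778,-0.4,-0.026667,-0.368889,-0.284444,-0.044444,-0.128889,-0.044444,0,-0.164444,-0.168889,-0.386667,-0.16,-0.142222
"Y",-0.248889,-0.276543,-0.039506,-0.039506,-0.288395,-0.161975,-0.051358,-0.355556,-0.023704,-0.327901,-0.25284,-0.039506,-0.114568,-0.039506,0,-0.146173,-0.150123,-0.343704,-0.142222,-0.12642
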