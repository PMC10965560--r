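arousal,valence,dominance,emotion,descartes
0,0,0,Neutral,FALSE
0,0,1,Other,FALSE
0,0,-1,Other,FALSE
0,1,0,Desire,TRUE
0,1,1,Other,FALSE
0,1,-1,Satisfaction,FALSE
0,-1,0,Other,FALSE
0,-1,1,Pessimism,FALSE
0,-1,-1,Other,FALSE
1,0,0,Admiration,TRUE
1,0,1,Other,FALSE
1,0,-1,Other,FALSE
1,1,0,Joy,TRUE
1,1,1,Generosity,FALSE
1,1,-1,Love,TRUE
1,-1,0,Distressed,FALSE
1,-1,1,Anxious,FALSE
1,-1,-1,Hate,TRUE
-1,0,0,Other,FALSE
-1,0,1,Calm,FALSE
-1,0,-1,Other,FALSE
-1,1,0,Relaxed,FALSE
-1,1,1,Overconfident,FALSE
-1,1,-1,Relief,FALSE
-1,-1,0,Sadness,TRUE
-1,-1,1,Rejected,FALSE
-1,-1,-1,Other,FALSE
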