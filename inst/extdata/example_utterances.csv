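participant_id,text,job_performance,personality_looks,life_threat,other
S01,"Lose weight, fatty!",FALSE,FALSE,FALSE,TRUE
S02,"Fool, idiot!",TRUE,FALSE,FALSE,FALSE
S03,"Ugly, smelly, please die.",FALSE,TRUE,TRUE,FALSE
S04,"Don't you understand Japanese? Are you mute or deaf?",FALSE,FALSE,FALSE,TRUE
S05,"Go home, you idiot!",TRUE,FALSE,FALSE,FALSE
S06,"Please die.",FALSE,FALSE,TRUE,FALSE
S07,"You idiot. Hey, I'll kill you. Die, you son of a bitch!",TRUE,FALSE,TRUE,FALSE
S08,"Resign your job! I'll tell the owner to make you quit!",TRUE,FALSE,FALSE,FALSE
S09,"Useless!",TRUE,FALSE,FALSE,FALSE
S10,"Deadhead, we don't need you!",FALSE,FALSE,FALSE,TRUE
S11,"Resign by yourself. You're an eyesore!",TRUE,FALSE,FALSE,FALSE
S12,"I hope you quit.",TRUE,FALSE,FALSE,FALSE
S13,"Don't come to work anymore!",FALSE,FALSE,FALSE,TRUE
S14,"I know I shouldn't discriminate, but you're the one who didn't have children, so you can't think about others.",FALSE,FALSE,FALSE,TRUE
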