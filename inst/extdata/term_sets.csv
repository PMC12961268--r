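term_set,preferred_term
depression_ex_suicide,adjustment disorder with depressed mood
depression_ex_suicide,anhedonia
depression_ex_suicide,decreased interest
depression_ex_suicide,depressed mood
depression_ex_suicide,depression
depression_ex_suicide,depressive symptom
depression_ex_suicide,discouragement
depression_ex_suicide,feeling of despair
depression_ex_suicide,feelings of worthlessness
depression_ex_suicide,major depression
depression_ex_suicide,mixed anxiety and depressive disorder
depression_ex_suicide,perinatal depression
suicide_self_injury,completed suicide
suicide_self_injury,depression suicidal
suicide_self_injury,intentional overdose
suicide_self_injury,intentional self-injury
suicide_self_injury,self-injurious ideation
suicide_self_injury,suicidal behavior
suicide_self_injury,suicidal ideation
suicide_self_injury,suicide attempt
suicide_self_injury,suicide threat
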