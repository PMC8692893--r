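# Cysteine-pattern rule table for vNAR type classification.
# Types are evaluated in order; a sequence matching none (or lacking the
# canonical FR1 + FR3b cysteine pair, or carrying cysteines in HV2/FR3a or
# extra cysteines in FR1/FR3b) is classified "new".
# Fields per type:
#   cdr1_cys      exact number of CDR1 cysteines required
#   cdr3_cys_min  minimum number of CDR3 cysteines
#   cdr3_cys_even whether the CDR3 cysteine count must be even
#   fr2_cys       whether an FR2 cysteine is required (true) or forbidden (false)
#   fr4_cys       same for FR4
#   cdr1_trp      conserved CDR1 tryptophan required (true) / forbidden (false)
types:
  I:
    cdr1_cys: 0
    cdr3_cys_min: 2
    cdr3_cys_even: true
    fr2_cys: true
    fr4_cys: true
  III:
    cdr1_cys: 1
    cdr3_cys_min: 1
    cdr3_cys_even: false
    fr2_cys: false
    fr4_cys: false
    cdr1_trp: true
  II:
    cdr1_cys: 1
    cdr3_cys_min: 1
    cdr3_cys_even: false
    fr2_cys: false
    fr4_cys: false
    cdr1_trp: false
  IV:
    cdr1_cys: 0
    cdr3_cys_min: 0
    cdr3_cys_even: false
    fr2_cys: false
    fr4_cys: false
    cdr3_cys_max: 0
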