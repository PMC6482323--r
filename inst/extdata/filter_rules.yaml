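# False-positive filter rules for NER output. A mention is dropped iff one
# pattern matches its FULL surface (patterns are anchored by the filter).
# The comparison-expression rule removes letter-initial tokens carrying a
# comparison operator and a numeric tail, e.g. "P≤0.001" or "IC50=20".
- rule_id: comparison_expression
  pattern: '[A-Za-z][A-Za-z0-9-]*\s?(?:<=|>=|[<>=≤≥])\s?[0-9][0-9.]*'
  description: letter-initial token with comparison operator and numeric tail
- rule_id: bare_number
  pattern: '[0-9]+(?:\.[0-9]+)*'
  description: numbers are never drug names
- rule_id: percentage
  pattern: '[0-9]+(?:\.[0-9]+)*\s?%'
  description: percentages
- rule_id: p_value_word
  pattern: '[Pp][- ]?values?'
  description: the phrase "P value"
- rule_id: n_equals
  pattern: '[Nn]\s?=\s?[0-9]+'
  description: sample-size expressions
- rule_id: confidence_interval
  pattern: '(?:90|95|99)\s?%\s?CI'
  description: confidence-interval shorthand
- rule_id: fold_change
  pattern: '[0-9]+(?:\.[0-9]+)*-fold'
  description: fold-change expressions
- rule_id: phase_roman
  pattern: '[Pp]hase\s+[IViv]+'
  description: trial-phase phrases
- rule_id: generic_inhibitor
  pattern: '[Ii]nhibitors?'
  description: generic pharmacology word
- rule_id: generic_agonist
  pattern: '[Aa]gonists?'
  description: generic pharmacology word
- rule_id: generic_antagonist
  pattern: '[Aa]ntagonists?'
  description: generic pharmacology word
- rule_id: generic_receptor
  pattern: '[Rr]eceptors?'
  description: generic biology word
- rule_id: generic_protein
  pattern: '[Pp]roteins?'
  description: generic biology word
- rule_id: generic_gene
  pattern: '[Gg]enes?'
  description: generic biology word
- rule_id: generic_cell
  pattern: '[Cc]ells?'
  description: generic biology word
- rule_id: generic_tumor
  pattern: '[Tt]umou?rs?'
  description: generic oncology word
- rule_id: generic_cancer
  pattern: '[Cc]ancers?'
  description: generic oncology word
- rule_id: generic_therapy
  pattern: '[Tt]herap(?:y|ies)'
  description: generic treatment word
- rule_id: generic_treatment
  pattern: '[Tt]reatments?'
  description: generic treatment word
- rule_id: generic_dose
  pattern: '[Dd]os(?:e|es|age|ages|ing)'
  description: dosing vocabulary
- rule_id: generic_placebo
  pattern: '[Pp]lacebos?'
  description: trial vocabulary
- rule_id: generic_control
  pattern: '[Cc]ontrols?'
  description: trial vocabulary
- rule_id: generic_patient
  pattern: '[Pp]atients?'
  description: trial vocabulary
- rule_id: generic_survival
  pattern: '[Ss]urvival'
  description: outcome vocabulary
- rule_id: generic_efficacy
  pattern: '[Ee]fficacy'
  description: outcome vocabulary
- rule_id: generic_toxicity
  pattern: '[Tt]oxicit(?:y|ies)'
  description: outcome vocabulary
- rule_id: generic_response
  pattern: '[Rr]esponses?'
  description: outcome vocabulary
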