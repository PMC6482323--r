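# Combination cue rules. Each entry: a stable rule_id, a perl regular
# expression matched case-insensitively against article text, a label and a
# literal example string matching the pattern (used by the synthetic-corpus
# generator). Fully user-replaceable.
- rule_id: 1
  pattern: '\bcombined\s+with\b'
  label: combined with
  example: combined with
- rule_id: 2
  pattern: '\bplus\b'
  label: plus
  example: plus
- rule_id: 3
  pattern: '\bco-administration\s+of\b'
  label: co-administration of
  example: co-administration of
- rule_id: 4
  pattern: '\bco-administered\s+with\b'
  label: co-administered with
  example: co-administered with
- rule_id: 5
  pattern: '\bcoadministration\s+of\b'
  label: coadministration of
  example: coadministration of
- rule_id: 6
  pattern: '\bconcomitant(?:ly)?\s+with\b'
  label: concomitant with
  example: concomitant with
- rule_id: 7
  pattern: '\bconcurrent(?:ly)?\s+with\b'
  label: concurrent with
  example: concurrently with
- rule_id: 8
  pattern: '\bin\s+association\s+with\b'
  label: in association with
  example: in association with
- rule_id: 9
  pattern: '\b(?:in\s+)?combination\s+(?:of|with)\b'
  label: (in) combination of/with
  example: in combination with
- rule_id: 10
  pattern: '\btogether\s+with\b'
  label: together with
  example: together with
- rule_id: 11
  pattern: '\bfollowed\s+by\b'
  label: followed by
  example: followed by
- rule_id: 12
  pattern: '\badjuvant\s+to\b'
  label: adjuvant to
  example: adjuvant to
- rule_id: 13
  pattern: '\bsynergistic\s+with\b'
  label: synergistic with
  example: synergistic with
- rule_id: 14
  pattern: '\bin\s+synergy\s+with\b'
  label: in synergy with
  example: in synergy with
- rule_id: 15
  pattern: '\bsynergi[sz]e[sd]?\s+with\b'
  label: synergizes with
  example: synergizes with
- rule_id: 16
  pattern: '\badded\s+to\b'
  label: added to
  example: added to
- rule_id: 17
  pattern: '\bco-treatment\s+with\b'
  label: co-treatment with
  example: co-treatment with
- rule_id: 18
  pattern: '\bcotreatment\s+with\b'
  label: cotreatment with
  example: cotreatment with
- rule_id: 19
  pattern: '\bcombination\s+therapy\s+(?:of|with)\b'
  label: combination therapy of/with
  example: combination therapy with
- rule_id: 20
  pattern: '\bcombined\s+administration\s+of\b'
  label: combined administration of
  example: combined administration of
- rule_id: 21
  pattern: '\bin\s+conjunction\s+with\b'
  label: in conjunction with
  example: in conjunction with
- rule_id: 22
  pattern: '\balongside\b'
  label: alongside
  example: alongside
- rule_id: 23
  pattern: '\bcoupled\s+with\b'
  label: coupled with
  example: coupled with
- rule_id: 24
  pattern: '\bsupplemented\s+with\b'
  label: supplemented with
  example: supplemented with
- rule_id: 25
  pattern: '\bin\s+tandem\s+with\b'
  label: in tandem with
  example: in tandem with
- rule_id: 26
  pattern: '\bpaired\s+with\b'
  label: paired with
  example: paired with
- rule_id: 27
  pattern: '\balong\s+with\b'
  label: along with
  example: along with
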