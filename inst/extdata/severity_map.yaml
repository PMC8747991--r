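# Default harmonization of each resource's native interaction-severity
# vocabulary onto {minor, moderate, major_contraindicated}, plus the
# shared course-of-action vocabulary onto
# {no_action, monitor, modify_dosage, avoid}.
# Lookups are case-insensitive after whitespace trimming (curly
# apostrophes are normalized to straight ones), so keys are written in
# lower case. Sub-moderate labels (PEPID levels 1-2, UpToDate risk
# ratings A/B, a generic "minor" elsewhere) map to minor; they are a
# package convention for data that includes sub-moderate pairs.
severity:
  pepid:
    "1": minor
    "2": minor
    "3": moderate
    "4": major_contraindicated
    "5": major_contraindicated
  micromedex:
    "minor": minor
    "moderate": moderate
    "major": major_contraindicated
    "contraindicated": major_contraindicated
  uptodate:
    "a": minor
    "b": minor
    "c": moderate
    "d": major_contraindicated
    "x": major_contraindicated
  drugscom:
    "minor": minor
    "moderate": moderate
    "major": major_contraindicated
  medscape:
    "minor": minor
    "monitor closely": moderate
    "serious": major_contraindicated
    "serious - use alternative": major_contraindicated
  webmd:
    "minor": minor
    "monitor closely": moderate
    "serious": major_contraindicated
    "don't use together": major_contraindicated
action:
  "no action required": no_action
  "no action": no_action
  "monitor": monitor
  "monitor therapy": monitor
  "monitor closely": monitor
  "modify dosage": modify_dosage
  "modifying the dosage": modify_dosage
  "consider therapy modification": modify_dosage
  "avoid": avoid
  "avoid combination": avoid
  "don't use together": avoid
  "prevent concurrent use": avoid
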