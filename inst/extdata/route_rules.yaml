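# Route classification rulebook: keyword -> formulation label, per field.
# Fields are tried in the fixed precedence route > dose_form > drugname >
# dose_freq; within a field, matching is case-insensitive substring. The
# keyword sets live here rather than in code because FAERS free text drifts.
route:
  oral: [oral, "per os"]
  subcutaneous: [subcutaneous, subcut, subq, "sub-q"]
dose_form:
  oral: [tablet, tab.]
  subcutaneous: [solution, pen, injection, injectable, syringe]
drugname:
  oral: [rybelsus]
  subcutaneous: [ozempic, wegovy]
dose_freq:
  oral: [daily, qd]
  subcutaneous: [weekly, qw]
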