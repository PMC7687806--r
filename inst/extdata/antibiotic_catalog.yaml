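# Broad-spectrum antibiotic catalog used to define suspected-infection
# episodes. Keys under broad_spectrum are classes (or single products) mapped
# to the concrete drug names matched in medication records; edit freely and
# pass via antibiotic_catalog(path = ...).
broad_spectrum:
  carbapenems: [imipenem, imipenem/cilastatin, meropenem, ertapenem, doripenem]
  glycopeptides: [vancomycin, teicoplanin]
  quinolones: [ciprofloxacin, levofloxacin, moxifloxacin, ofloxacin]
  # printed combination kept verbatim; tazobactam combination added as the
  # marketed member of the class
  piperacillin/sulbactam: [piperacillin/sulbactam, piperacillin/tazobactam]
  ceftazidime: [ceftazidime]
  cefepime: [cefepime]
  linezolid: [linezolid]
  tigecycline: [tigecycline]
  daptomycin: [daptomycin]
  fosfomycin: [fosfomycin]
excluded:
  - ampicillin
  - cefazolin
  - cefuroxime
  - colistin
  - metronidazole
  - erythromycin
  - trimethoprim/sulfamethoxazole
  - cotrimoxazole
  - azithromycin
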