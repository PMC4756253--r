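# Sample medication-education content (synthetic, illustrative only).
# Stands in for a live drug-information service: generic class-level
# information about common antihypertensive drug classes, looked up by
# drug or class name. Not medical advice.
- names: [amlodipine, nifedipine, felodipine]
  class: calcium channel blocker
  info: >
    Relaxes blood-vessel muscle so vessels widen and blood pressure
    falls. Common side effects include ankle swelling, flushing and
    headache. Take at the same time every day; do not stop suddenly
    without consulting your clinician.
- names: [losartan, valsartan, candesartan]
  class: angiotensin receptor blocker
  info: >
    Blocks the hormone signal that narrows blood vessels. Usually well
    tolerated; dizziness can occur after the first dose. Report
    persistent lightheadedness to your clinician.
- names: [enalapril, ramipril, lisinopril]
  class: ACE inhibitor
  info: >
    Lowers blood pressure by blocking production of a vessel-narrowing
    hormone. A dry cough is the most common side effect. Avoid potassium
    supplements unless your clinician advises them.
- names: [hydrochlorothiazide, indapamide]
  class: thiazide diuretic
  info: >
    Helps the kidneys remove excess salt and water. Take in the morning
    to avoid night-time urination; your clinician may monitor potassium
    and sodium levels.
- names: [atenolol, bisoprolol, metoprolol]
  class: beta blocker
  info: >
    Slows the heart and reduces its workload. May cause tiredness or
    cold hands; do not stop abruptly, as blood pressure and heart rate
    can rebound.
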