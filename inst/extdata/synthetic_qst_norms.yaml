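# SYNTHETIC QST reference norms (single stratum), for tests and examples.
# These are NOT published normative values; they only share the schema and
# plausible magnitudes. Replace with your own norms table for real analyses.
# mean/sd/ref_* are in the analysis domain (log10 where domain: log10);
# sign = +1 means a larger transformed value indicates gain of function.
parameters:
  - {param: CDT, stratum: all, domain: log10, sign: -1, mean: 0.10, sd: 0.20}
  - {param: WDT, stratum: all, domain: log10, sign: -1, mean: 0.45, sd: 0.18}
  - {param: TSL, stratum: all, domain: log10, sign: -1, mean: 0.70, sd: 0.20}
  - {param: CPT, stratum: all, domain: linear, sign: 1, mean: 12.0, sd: 8.0}
  - {param: HPT, stratum: all, domain: linear, sign: -1, mean: 44.0, sd: 3.0}
  - {param: MDT, stratum: all, domain: log10, sign: -1, mean: 0.45, sd: 0.35}
  - {param: MPT, stratum: all, domain: log10, sign: -1, mean: 1.85, sd: 0.35}
  - {param: MPS, stratum: all, domain: log10, sign: 1, mean: 0.00, sd: 0.45}
  - {param: WUR, stratum: all, domain: log10, sign: 1, mean: 0.35, sd: 0.20}
  - {param: PPT, stratum: all, domain: log10, sign: -1, mean: 2.55, sd: 0.15}
  - {param: VDT, stratum: all, domain: log10, sign: 1, mean: 0.88, sd: 0.05}
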