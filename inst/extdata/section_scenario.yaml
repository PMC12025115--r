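# Three-cluster scenario matching the published section-cluster summary
# statistics (centers in %, total metric variance, cluster sizes).
seed: 20250329
prep: section
clusters:
  - name: SC I
    center: {C: 20.07, O: 46.05, Ca: 19.80, Mg: 1.60, Traces: 12.48}
    total_variance: 0.1063
    "n": 14
  - name: SC II
    center: {C: 9.47, O: 61.96, Ca: 21.72, Mg: 3.94, Traces: 2.90}
    total_variance: 0.2553
    "n": 41
  - name: SC III
    center: {C: 8.06, O: 53.49, Ca: 33.82, Mg: 2.88, Traces: 1.74}
    total_variance: 0.2567
    "n": 45
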