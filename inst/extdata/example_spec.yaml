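cells:
- 'n': N3
  h: H0
  cardiac: absent
  count: 3
- 'n': N1
  h: H1
  cardiac: present
  count: 2
- 'n': N0
  h: H1
  cardiac: absent
  count: 4
- 'n': N0
  h: H3
  cardiac: unknown
  count: 2
- 'n': N2
  h: H3
  cardiac: absent
  count: 1
n_unscorable: 2
missingness: []
seed: 42
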