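{
  "features": ["db2dec2sd", "bior33dec1max", "bior33dec3mn", "sym5dec2mn"],
  "coefficients": {
    "db2dec2sd": 0.2456044,
    "bior33dec1max": 1.1709781,
    "bior33dec3mn": 0.0399379,
    "sym5dec2mn": -0.0691719
  },
  "constant": -541.1768021,
  "cutoff": -0.6299,
  "positive_side": "above"
}
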