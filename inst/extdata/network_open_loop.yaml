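name: open_loop+follower
neurons:
- I_dec
- I_decTON
- IE
- E_dec
- EI_TON
- EI
- 'ON'
- I_inc
external_inputs: 1.0
connections:
- pre: IE
  post: IE
  kinetic: 3
  P: 600.0
  plastic_tag: none
- pre: IE
  post: E_dec
  kinetic: 1
  P: 5000.0
  plastic_tag: P_f
- pre: E_dec
  post: IE
  kinetic: 1
  P: -2200.0
  plastic_tag: none
- pre: E_dec
  post: I_dec
  kinetic: 4
  P: -250.0
  plastic_tag: none
- pre: E_dec
  post: EI_TON
  kinetic: 4
  P: 8000.0
  plastic_tag: none
- pre: E_dec
  post: EI
  kinetic: 4
  P: -500.0
  plastic_tag: none
- pre: I_decTON
  post: I_decTON
  kinetic: 3
  P: 40.0
  plastic_tag: none
- pre: I_decTON
  post: I_dec
  kinetic: 4
  P: 500.0
  plastic_tag: none
- pre: I_dec
  post: E_dec
  kinetic: 1
  P: -1500.0
  plastic_tag: none
- pre: I_dec
  post: I_decTON
  kinetic: 3
  P: -5000.0
  plastic_tag: none
- pre: I_dec
  post: EI
  kinetic: 4
  P: -350.0
  plastic_tag: none
- pre: EI_TON
  post: EI_TON
  kinetic: 3
  P: 40.0
  plastic_tag: none
- pre: EI_TON
  post: EI
  kinetic: 2
  P: 400.0
  plastic_tag: none
- pre: EI
  post: I_decTON
  kinetic: 2
  P: 200.0
  plastic_tag: none
- pre: EI
  post: EI_TON
  kinetic: 2
  P: 1280.0
  plastic_tag: none
- pre: 'ON'
  post: IE
  kinetic: 4
  P: 1280.0
  plastic_tag: none
- pre: EI
  post: I_inc
  kinetic: 2
  P: 1280.0
  plastic_tag: none
- pre: E_dec
  post: I_inc
  kinetic: 2
  P: -1500.0
  plastic_tag: none
- pre: I_inc
  post: I_inc
  kinetic: 3
  P: 80.0
  plastic_tag: P_a
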