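condition_max_out: yes
center: no
terms:
- name: ArcA
  lambda: 2.0
- name: ReciprocityA
  lambda: 2.0
- name: AinSA
  lambda: 2.0
- name: AoutSA
  lambda: 2.0
- name: ATA-T
  lambda: 2.0
- name: A2PA-T
  lambda: 2.0
- name: Sender
  attribute: gender
  lambda: 2.0
- name: Receiver
  attribute: gender
  lambda: 2.0
- name: Interaction
  attribute: gender
  lambda: 2.0
- name: Sender
  attribute: ps
  lambda: 2.0
- name: Receiver
  attribute: ps
  lambda: 2.0
- name: Sender
  attribute: knowledge
  lambda: 2.0
- name: Receiver
  attribute: knowledge
  lambda: 2.0
- name: Difference
  attribute: knowledge
  lambda: 2.0
- name: Sender
  attribute: norms
  lambda: 2.0
- name: Receiver
  attribute: norms
  lambda: 2.0
- name: Difference
  attribute: norms
  lambda: 2.0
- name: Sender
  attribute: talking
  lambda: 2.0
- name: Receiver
  attribute: talking
  lambda: 2.0
- name: Difference
  attribute: talking
  lambda: 2.0
- name: PSTalkingSender
  lambda: 2.0
- name: PSTalkingReceiver
  lambda: 2.0
- name: In2StarAX
  lambda: 2.0
- name: Out2StarAX
  lambda: 2.0
- name: TXAXarc
  lambda: 2.0
- name: L3XAX
  lambda: 2.0
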