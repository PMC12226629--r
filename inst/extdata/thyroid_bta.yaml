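# Search strategy for neck and thyroid ultrasound reports: fourteen classes
# covering common diffuse and focal thyroid pathology plus British Thyroid
# Association (BTA) U1-U5 nodule gradings.
#
# Shorthand: &, |, ¬ and ~X stand for AND, OR, NOT and the bidirectional
# word-proximity operator NEAR/X; '*' and '?' are wildcard modifiers.
# Double-quoted names reference earlier classes (derived classes).
#
# Two BTA exclusion spellings are normalised for standardised text, where
# '/' is a word separator: the combined grading "u2/u3" is written as the
# adjacent phrase 'u2 u3' (after standardisation "u2/u3" reads "u2 u3"),
# and 'u2~1?3' catches the spaced variants "u2 3", "u2 or 3", "u2 u3".
# The examination classes disable negation: "no abnormal lymph nodes" still
# documents that the lymph nodes were examined.
name: neck and thyroid ultrasound
headers: [clinical history, findings]
classes:
  - name: Thyroid examination
    query: thyroid*
    sections: [findings]
    negation: false
  - name: Lymph node examination
    query: 'lymph* | (node & ¬thyroid* node)'
    sections: [findings]
    negation: false
  - name: Thyroid nodule(s)
    query: >-
      (nodul* & ¬(nodul*~2cartilage | nodul*~2parotid | nodule*~2salivary |
      nodul*~2submandibular)) | (cyst* & ¬(thyroglossal cyst | cyst*~2parotid |
      cyst*~2salivary | cyst*~2submandibular | cyst*~1sebaceous |
      cyst*~1inclusion | cyst*~1lymph* | cyst*~1node)) | thyroid~4lesion* |
      thyroid~1node* | adenoma
    sections: [findings]
  - name: Multiple thyroid nodules
    query: >-
      (nodules & ¬(nodules~2cartilage | nodules~2parotid | nodules~2salivary |
      nodules~2submandibular)) | (cysts & ¬(thyroglossal cysts |
      cysts~2parotid | cysts~2salivary | cysts~2submandibular |
      cysts~2sebaceous | cysts~2inclusion | cysts~2lymph* | cysts~2node)) |
      thyroid~4lesions | thyroid~1nodes | multi?nodul* | nodul*~2both |
      other~2nodul* | second*~2nodul* | (superior~3nodul* & inferior~3nodul*) |
      (nodule*~3left & nodule*~3right) | (nodule*~3left & nodule*~3isthmus) |
      (nodule*~3right & nodule*~3isthmus) | mng
    sections: [findings]
  - name: Altered thyroid echotexture
    query: >-
      thyroiditis | grav?s | heterogen*~2echo* | heterogen*~2thyroid |
      heterogen*~1texture | inflamed*
    sections: [findings]
  - name: Goitre
    query: >-
      goit?r? | mng | multi?nodul* thyroid | enlarged~2thyroid |
      (enlarged~2gland & ¬enlarged~2parathy*) | enlarged~2lobe | hyperplasia
    sections: [findings]
  - name: Previous thyroid surgery
    query: >-
      thyroidectomy | lobectomy | isthmusectomy |
      (surgery & ¬refer*~2surgery) | resect* | incomplete~2thyroid | post?op |
      bed | hemiagenesis
    sections: [findings, clinical history]
  - name: BTA U1
    query: u1
    sections: [findings]
  - name: BTA U2
    query: 'u2 & ¬(u2 u3 | u2~1?3)'
    sections: [findings]
  - name: BTA U3
    query: 'u3 & ¬(u3 u4 | u3~1?4 | u2 u3 | u2~1?3)'
    sections: [findings]
  - name: BTA U4
    query: 'u4 & ¬(u4 u5 | u4~1?5 | u3 u4 | u3~1?4)'
    sections: [findings]
  - name: BTA U5
    query: 'u5 & ¬(u4 u5 | u4~1?5)'
    sections: [findings]
  - name: Solitary thyroid nodule
    query: '"Thyroid nodule(s)" & ¬"Multiple thyroid nodules"'
    derived: true
  - name: Normal thyroid
    query: >-
      "Thyroid examination" & ¬("Thyroid nodule(s)" |
      "Altered thyroid echotexture" | "Goitre" | "Previous thyroid surgery")
    derived: true
post_processing:
  - {if: BTA U2, then: Thyroid nodule(s), set_to: true}
  - {if: BTA U3, then: Thyroid nodule(s), set_to: true}
  - {if: BTA U4, then: Thyroid nodule(s), set_to: true}
  - {if: BTA U5, then: Thyroid nodule(s), set_to: true}
  - {if: Multiple thyroid nodules, then: Thyroid nodule(s), set_to: true}
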