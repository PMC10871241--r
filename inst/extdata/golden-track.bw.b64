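JvyPiAQAAgBYAQAAAAAAAJQBAAAAAAAAJgUAAAAAAAAAAAAAAAAAAAAAAAAwAQAAAAAAAFgFAAAAAAAAAAAAABMBAAAAAAAAmgUAAAAAAABjBwAAAAAAAEwEAAAAAAAA1wcAAAAAAABzCAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAANoMAAAAAAAAAAAAQNr+tj8AAADggNgjQADIo9O7R9BAqIYmpxdf+0CRjMp4AAEAAAQAAAAIAAAAAgAAAAAAAAAAAAAAAAAAAAEAAgBjdGcxAAAAAKAPAABjdGcyAQAAAMQJAAACAAAAeJw91HtIFlYcxvHzqpX3Ul+1dTNEsGiliK1N8j2/U0lpsjfKEoOyC13YZr1Ws+kEu5KRUUGmREKWtLbXbnR5e7tpq0QKu5hkl2kXCG29NbRya/i6PY9BB758/jicA+fAOUp9GsWD1edhUY5+Y1Gd+3ehiWh8bpWmS9D1lGBDV6ADDQMN/RG1XPLYaAXqsr0QegBFxjrlPLyC3qZFG9rO/T1hhnrRtVd7hIZYlHL8/V7oZCRV1UJz0Y5qi9CNyFL8Uugu1Nb4QehvaGXgC6F/oOXTP2gvTPBRquMXm9AZaFPkLKF5aJhyCd2AHieFmMuwE42ZF2yo8lXK2l0gNAllRnnkK7gI/dzcJ/0i+8UOoZVoyvECobUo7Z5N6Gk0c3SEpk3ozd5WoZ3ovzyvpv+iVv9GobF+Sl19elLTZJRwY5X8AEtRkV+60EPoY56PeQ0jBiiV6v5eaAw6cqJM6NfoUEmZ0Lmoobxe6GoUKhuFliFX1hemHfoMVOro7OGGRqOwOeGGTkEjx2Rpmo+yKyuFFiFPUI7QUtRW0ir0MHpbe0voOeRfHGDoXXTRHW3oX2iJ0yW0D9nSnULjBil12xllEmAKam8INTQXZWZuFupA8Val6+FD1Bz0UWgfWhxvNXSoP9aW5wv9Ej2pGyF0MgrPWaRpBppkLxI6H1049krTn9C4QKf+Fd5G7oY4oa1IBZ4S+g5lb7usaUyAUmbIMEOnoaMx0eY4vIoGXR9legK4Tqkbvc+FxiBJOqNpBmrucaVmw7XIdeyJ0Aq0zPtIamAd0k3hhrag9lObhA4IwnkmbJMomIamdjmFzkGvF2yR+9A3GG/1n0JNE1FI7lqhc1GLw6tpPuq1dAotQ5Hrn6fS/eg7vwhzAp5HCwOGmDr4CKVndQn1cO7boYZaQ3DviY0yES5F6zvuSb+o3LpOaDWyv4vX9CTqsbYJfYj+HH9Y0x50MD9FaGioUtvtN4V+g0qrCoXORGMzkjVdhrrHBRq6E+3eWiC0HNXWPJB+0YPgHBs9i+IKrwitR/NvJQq9g947SoQ+Q001FzTtRksf+5pR+CuT0Wb3aU3taN+aMEP5j3p6B5v/AU9rN5N4nGNkgIBARgY4YGTgANPqILbpN3sQHQ7EFqGrHEB0NhCXiix3ANFTgfiC1Vn7H0CaGWjGO6dlDiCaF4hXrON3ANHGQPxWy8QBRIPsEdNb6AAAStcRbeCsaCQAAQAAAgAAAAAAAAAAAAAAAAAAAAEAAABRAQAAJgUAAAAAAAAABAAAAAAAAAEAAgAAAAAAAAAAAAAAAAB8DwAAmAEAAAAAAAA4AwAAAAAAAAEAAAAAAAAAAQAAAFEBAADQBAAAAAAAAFYAAAAAAAAAEQAAAHicY2CAAGFGBobvQPrKnjd271zFHd1nnHJhqLJ3g8mpMTEwfAKy09y/2t898dVh2/5Gl9ArG1xB8iA5S2YGhktA9vPldg63jHgd1+5Z4aKsIwbWD5LzYWFg+A1keysI21df+uewRqnfZT/DVbB+kFw8KwPDKiC7isXT4Wcuk2Ohlp+LwoVusDxIroiNgeEgkC2rEWK/Ikja8UVav4tTDT/YfJBcKzsDw2cgW12EwX73TnHHJ8ZHXRy2WYLlQXIzOBgYdgDZQpEJ9onqIo5933xdLvxZAzYfJLeak4FhNpAd3r7X3lFAytH3Vb6Lw5UfYHmQ3D4uiP2Xvm23ZT8i53htVanLn4tvwfIguYvcDAwtQPa9jU0O9meFHD9LSLqUTzMFy4PknvAwMHwFskXLH9ru8JNwnPO62uVTykWwPEjuOy8kfP0/q9uD5OWFS10ENkLCFyTHxQ8Jv2s8kXaftLkcc/60uWx2OA6WB8ktAOI4ILt552b7aUWCjmrBWi7Lvu9wBQDws4IBeJxjZIAAYUYGhg1A+oLVWXuL0FUOMzaKuhi3ybsyQuXUmBgY7IDst1omDmJ6Cx1WGxQ6X1pT6wIAbWgOC+CsaCQAAQAAAgAAAAAAAAAAAAAAAAAAAAEAAAAmAgAAYwcAAAAAAAAABAAAAAAAAAEAAgAAAAAAAAAAAAAAAACgDwAAngUAAAAAAACIAQAAAAAAAAEAAAAAAAAAAQAAACYCAAAmBwAAAAAAAD0AAAAAAAAABQAAAHicY2CAAB8WBoZtzAwMV/a8sXvnKu54lXehq7YKmztMbgYHA4MYUF5dhMF+RZC04+VVHa61Zz65geRBck94GBiuMjEwXPq23Zb9iJxjzrI411lbj4DlQXIL+BkYvIHy13gi7Xb4STgeD9d2jbLqcQMAnjshanicY2SAAB8WBoZ3QPqC1Vl7i9BVDof/Brqkf4xzBQBd+wkd4KxoJAABAAACAAAAAAAAAAAAAAAAAAAAAQAAAEwEAABzCAAAAAAAAAAEAAAAAAAAAQACAAAAAAAAAAAAAAAAAKAPAADbBwAAAAAAAHUAAAAAAAAAAQAAAAAAAAABAAAATAQAAFAIAAAAAAAAIwAAAAAAAAAm/I+I
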